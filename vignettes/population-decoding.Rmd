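---
title: "Decoding oculomotor behavior from neuronal populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding oculomotor behavior from neuronal populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcdecode)
```

## The task and the behavior space

The package models a delayed memory saccade task on a Cartesian grid.
A trial begins with fixation at one of 3 × 3 grid nodes spaced 8 deg
apart; a target flashes for 300 ms at one of the 8 neighboring nodes; the
animal holds fixation through a memory delay of 1300 ± 200 ms (uniform
jitter); at the go cue it saccades in darkness to the remembered location,
then holds two further 500 ms fixations (the second with the target
reilluminated). The landing position is the exact vector sum of the
fixation position and the saccade displacement, so landing positions tile
a 5 × 5 grid and each trial realizes one of 9 × 8 = 72 combinations.
`behavior_space()` enumerates these sets and the composition map;
`simulate_task()` draws balanced sessions — every combination exactly once
per block, independently permuted per block — so an 11-block session has
792 trials and a uniform behavioral prior by construction. Only correct
trials are generated; there is no error-trial model.

Two timing quantities have no protocol-specified distribution: the
fixation-acquisition latency and the saccade reaction time. Both default
to a truncated normal (mean 200 ms, SD 30 ms, floor 80 ms), a conventional
primate reaction-time shape; both are configurable, and because every
trial stores its ground-truth event times no downstream stage depends on
detecting them. A velocity-threshold saccade detector is deliberately out
of scope: synthetic trials carry exact saccade onsets.

## The generative population model

`make_population()` builds neurons whose instantaneous rate is

> rate = (baseline + depth · vm(θ − θ_pref)) · epoch gain · position gain

with `vm` a von Mises bump (unit peak, concentration κ), the position gain
planar (1 + gₓx + g_y y, floored at 0), and a multiplicative epoch profile.
Defaults: baseline 5–15 spikes/s, depth 8–24 spikes/s, κ = 2, gain slopes
±0.02 per deg, epoch gains fixation 1.0, visual 2.5, memory 1.6,
perisaccadic 2.0 (from 80 ms before to 100 ms after saccade onset), then a
decaying postsaccadic profile (1.5, 1.1). Three structural choices matter
for what the decoder can see:

* the direction term is gated off before target onset — the planned
  direction cannot drive a neuron before the plan exists — so direction
  decoding is at chance during fixation by construction;
* the gain field is driven by the presaccade eye position until the
  saccade lands and by the postsaccade position afterwards;
* rates are piecewise constant across epochs. Continuous ramps are not
  modeled; with 250 ms counting windows the decoder cannot resolve
  sub-epoch rate shapes, so the extra realism would not change what the
  tests can show.

Spike times are a piecewise-constant-rate Poisson process
(`simulate_spikes()`), matching the decoder's likelihood family. Each
(neuron, trial) pair has its own RNG stream derived from the master seed,
so enlarging a population never perturbs existing spike trains.
`simulate_counts()` draws window counts directly (inverse-CDF from a
counter-based uniform per pair) for large populations where materializing
spike times is wasteful.

The von Mises family is a choice, not a claim: any circular bell shape
would serve, and κ = 2 gives tuning widths typical of parietal direction
tuning. The generator makes no attempt to reproduce noise correlations,
refractoriness, non-Poisson dispersion, or continuous-time response
latencies; passing tests therefore demonstrate correctness of the
inference machinery under the model's own assumptions, not fidelity of
real cortical data to those assumptions.

## The decoder

Tuning curves are empirical means per behavior (`fit_tuning()`); the
Poisson likelihood needs only the mean, the truncated-Gaussian variant
adds the unbiased (n − 1) variance and renormalizes the Gaussian by its
continuous integral over the positive half-line (closed form via the
Gaussian tail function). Population likelihoods are products over neurons,
accumulated as log sums: with hundreds of neurons a probability-space
product would underflow long before the posterior is formed.

Two numerical floors keep every likelihood finite: means are floored at
0.05 counts and variances at 0.25 before evaluation. A behavior whose
training counts are all zero would otherwise assign probability zero to
any nonzero test count and poison the posterior. The floors are
configurable arguments of every decoding function, and the convention
0⁰ = 1 applies at the exact-zero boundary (a silent neuron observes zero
spikes with certainty).

Decoding is leave-one-out cross-validated throughout: for each trial both
the tuning curves and (by default) the occurrence prior are refit on the
remaining trials. Refitting the prior inside the fold is the stricter
reading of cross-validation; with balanced sessions the difference from a
session-wide prior is one trial in 792, and both modes are exposed
(`prior_mode`). The implementation exploits the fact that removing one
trial only changes the statistics of that trial's own behavior, so a
session decode costs one matrix product plus an O(trials × neurons)
correction rather than 792 refits.

Two decompositions of the 72-way problem are provided. The default
(`mode = "joint"`) fits tuning per combination and forms a single joint
posterior; position and direction are its marginals, and the landing
position's posterior sums the joint posterior over all combinations that
compose to the same node — the vector-sum dependency expressed as
marginalization. The alternative (`mode = "marginal"`) fits position and
direction models separately (9-way on 88 trials each, 8-way on 99 trials
each, in a full session), composing their independent posteriors for the
landing position; it has better-conditioned tuning estimates per behavior
when windows carry few spikes. The joint mode is the default because the
landing-position marginalization is exact there.

MAP ties are broken uniformly at random from a dedicated seeded stream
(ties are exact only in degenerate cases, e.g. perfectly uniform
posteriors, but those are precisely the chance-level cases where a
deterministic tie-break would bias accuracy). NPC accuracy averages
per-behavior fractions correct without trial-count weights; the bootstrap
(default 1000 resamples) resamples trials uniformly across the session,
dropping from a replicate's average any behavior absent from it;
stratified resampling is available as an option.

## Time courses, epoch summaries, onsets and peaks

`npc_timecourse()` repeats the full decode in causal boxcar windows —
count at time t covers [t − 250, t), strictly the past — sliding in 10 ms
steps, so inference always uses intervals of identical length. 250 ms is
short against the task epochs but long enough to accumulate decodable
counts. Counts are assembled once into a binned cumulative array, making
each window a column difference; the same bootstrap resamples are reused
at every step so replicate traces are coherent in time and epoch
summaries can be bootstrapped from them. Windows that poke outside a
trial's recorded span are flagged `clipped`, never padded.

Epoch accuracy is the root mean square of the trace between two events —
the area under the time course normalized by epoch length — which makes
epochs of different durations comparable; epoch bounds may be given as
event names (resolved to session means) or times.

Onset/peak detection smooths the trace with a truncated Gaussian kernel
(250 ms support; SD 50 ms, a quarter of the support, so the truncation
discards only far tails) renormalized at the series edges, then compares
the mean central-difference derivative over 100 ms after versus before
each step: the onset maximizes (after − before), the peak the opposite.
The kernel SD and derivative span are reported parameters, not canonical
values. A trace is declared structureless — marks `NA` with a reason —
when the smoothed range is below 7 times the smoothed noise level (noise
SD estimated from first differences and propagated through the kernel);
7 was calibrated by simulation so pure-noise traces yield spurious marks
in well under 5% of runs while genuine ramps of a few noise SDs are
retained.

## Recursive Neuronal Elimination

`rne_rank()` greedily removes, at each iteration, the neuron whose removal
maximizes the remaining population's objective: the decoding accuracy
averaged across the three behaviors, each taken as the RMS over its
mediating epoch — memory for direction, fixation for the presaccade
position, fixation II for the landing position. One neuron is removed per
iteration by default; a `batch` option removes the k jointly
least-important by single-removal score (exhaustive subset search is
combinatorial and out of scope). Objective ties are resolved toward the
lower neuron id, deterministically. Sessions must provide at least
`min_trials` (default 9) trials per behavior.

The default objective evaluates one 250 ms window per epoch — the RMS of
a single point is the point — because the candidate loop is the cost
hotspot: a full time course per candidate would multiply the work by the
number of windows. Supplying several window ends per epoch recovers a
denser epoch RMS. The per-neuron log-likelihood contributions (including
each neuron's own leave-one-out correction) are additive, so candidate
removals are evaluated by subtracting a precomputed slice rather than
re-decoding, and the greedy pass over N neurons costs O(N²) subtractions.

One subtlety the redundancy tests respect: a neuron whose *tuning* is
duplicated but whose spike noise is independent is not information-free —
its counts still average noise — so greedy elimination may legitimately
keep both copies while dropping a weakly informative unique neuron. True
redundancy means duplicated *responses*; with an exact response copy in
the population, elimination removes one copy first, as the tests verify.

`bias_correct()` implements the sampling-bias correction: an empirical
time course is rescaled so its mean accuracy over a reference epoch
matches an optimized subset's value, then clipped to [chance, 1]; the
scale factor is reported alongside.

## Reproducibility and problem sizes

All randomness flows from integer seeds through deterministic sub-stream
derivation (task schedule, spike streams, tie-breaks, bootstraps are
separate streams); identical configurations give byte-identical artifacts,
which `run_pipeline()` writes as delimited text with metadata headers. The
shipped tests and the acceptance script run on desk-scale problems chosen
to exercise every claim with comfortable statistical margins: full
792-trial sessions, populations of 20 neurons for chance-level and
model-agreement checks, 50 for the accuracy-versus-size curve, and 300
strongly tuned neurons for the near-certain direction posterior; bootstrap
counts of 200–1000 depending on the precision the check needs.

## Known limitations

* The independence assumption of the likelihood is also the independence
  of the generator; correlation-aware likelihoods are not implemented.
* Epoch-gain profiles are piecewise constant, so the generator cannot
  produce within-epoch latency structure finer than the counting window.
* The accuracy bootstrap treats trials as exchangeable; it does not model
  slow drifts within a session.
* The marginal decoding mode composes position and direction posteriors
  under independence, which is exact for the generator but only an
  approximation whenever responses couple the two variables within a
  window.
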