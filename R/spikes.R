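# Spike-train generation: piecewise-constant-rate Poisson processes whose
# rate follows the population's tuning model across task epochs.

# Break one trial into constant-rate segments. Returns a data.frame with
# start/end (ms on the trial clock), the epoch-gain column, whether the
# target has been shown, and which eye position drives the gain field.
# Perisaccadic gain timing (lead/tail) is shared across the population
# (taken from the first neuron).
trial_segments <- function(trial, peri_lead_ms, peri_tail_ms) {
  peri_start <- max(0, trial$saccade_onset - peri_lead_ms)
  peri_end <- min(trial$trial_end, trial$saccade_onset + peri_tail_ms)
  bp <- sort(unique(pmin(pmax(
    c(0, trial$target_on, trial$target_off, trial$go_cue,
      peri_start, peri_end, trial$fixation1_acquired,
      trial$fixation2_acquired, trial$trial_end), 0), trial$trial_end)))
  start <- bp[-length(bp)]
  end <- bp[-1]
  keep <- end > start
  start <- start[keep]
  end <- end[keep]
  mid <- (start + end) / 2
  epoch <- ifelse(mid >= peri_start & mid < peri_end, "g_perisaccadic",
           ifelse(mid < trial$target_on, "g_fixation",
           ifelse(mid < trial$target_off, "g_visual",
           ifelse(mid < peri_start, "g_memory",
           ifelse(mid < trial$fixation2_acquired, "g_postsaccadic1",
                  "g_postsaccadic2")))))
  data.frame(start = start, end = end, epoch = epoch,
             target_shown = mid >= trial$target_on,
             post_eye = mid >= trial$fixation1_acquired)
}

# Rate matrix (neurons x segments) for one trial.
segment_rates <- function(pop, space, trial, segs) {
  pre_xy <- c(trial$pre_x, trial$pre_y)
  post_xy <- c(trial$post_x, trial$post_y)
  matrix(vapply(seq_len(nrow(segs)), function(s) {
    neuron_rates(pop, space, trial$dir_id,
                 if (segs$post_eye[s]) post_xy else pre_xy,
                 segs$epoch[s], segs$target_shown[s])
  }, numeric(nrow(pop))), nrow = nrow(pop))
}

#' Simulate spike trains for a session
#'
#' Draws spike times for every neuron on every trial from a
#' piecewise-constant-rate Poisson process. The rate in each trial segment is
#' baseline x epoch gain x direction tuning x eye-position gain (see
#' [make_population()]); segment boundaries come from the trial's event
#' times, with the perisaccadic gain active from `peri_lead_ms` before
#' saccade onset to `peri_tail_ms` after it, and the gain field driven by the
#' presaccade eye position until the saccade lands and by the postsaccade
#' position afterwards.
#'
#' Each (neuron, trial) pair uses its own RNG stream derived from `seed`, so
#' enlarging the population leaves the spike trains of existing neurons
#' unchanged.
#'
#' @param pop A [make_population()] object.
#' @param trials A trial table from [simulate_task()].
#' @param seed Integer master seed.
#' @return A tibble of spikes: `trial_id`, `neuron_id`, `time_ms` (trial
#'   clock), sorted by trial, neuron, time.
#' @export
simulate_spikes <- function(pop, trials, seed = 1) {
  check_trials(trials)
  space <- attr(trials, "space")
  if (is.null(space)) {
    abort("`trials` must carry a behavior space (simulate_task output or read_trials).",
          class = "npc_invalid_input")
  }
  lead <- pop$peri_lead_ms[1]
  tail_ms <- pop$peri_tail_ms[1]
  n_neuron <- nrow(pop)

  out <- vector("list", nrow(trials))
  for (t in seq_len(nrow(trials))) {
    trial <- trials[t, ]
    segs <- trial_segments(trial, lead, tail_ms)
    rates <- segment_rates(pop, space, trial, segs)  # N x S
    durs <- (segs$end - segs$start) / 1000
    lam <- rates * rep(durs, each = n_neuron)
    ids <- integer(0)
    times <- numeric(0)
    for (i in seq_len(n_neuron)) {
      set.seed(derive_seed(seed, pop$neuron_id[i], trial$trial_id))
      k <- rpois(length(durs), lam[i, ])
      tot <- sum(k)
      if (tot > 0) {
        tt <- rep(segs$start, k) + runif(tot) * rep(segs$end - segs$start, k)
        ids <- c(ids, rep(pop$neuron_id[i], tot))
        times <- c(times, sort(tt))
      }
    }
    out[[t]] <- tibble::tibble(trial_id = trial$trial_id, neuron_id = ids,
                               time_ms = times)
  }
  spikes <- dplyr::bind_rows(out)
  attr(spikes, "neuron_ids") <- pop$neuron_id
  spikes
}

#' Simulate window spike counts directly
#'
#' Draws the Poisson spike count of every neuron on every trial in a single
#' counting window, without materializing spike times. The count mean is the
#' integral of the same piecewise-constant rate used by [simulate_spikes()]
#' over the window. Counts use one deterministic stream per (neuron, trial)
#' pair (inverse-CDF sampling from a counter-based uniform), so results are
#' reproducible and unaffected by population size. Useful for large
#' populations where full spike trains are not needed.
#'
#' @inheritParams simulate_spikes
#' @param align_event Event name the window is aligned to.
#' @param window Numeric `c(start, end)` in ms relative to the event
#'   (e.g. `c(-250, 0)` for a causal window ending at the event).
#' @return A count table: tibble with `trial_id`, the behavior labels
#'   (`combo_id`, `pos_id`, `dir_id`, `post_id`), and one integer column per
#'   neuron named `n<id>`.
#' @export
simulate_counts <- function(pop, trials, align_event = "go_cue",
                            window = c(-250, 0), seed = 1) {
  check_trials(trials)
  space <- attr(trials, "space")
  lead <- pop$peri_lead_ms[1]
  tail_ms <- pop$peri_tail_ms[1]
  n_neuron <- nrow(pop)
  lam <- matrix(0, nrow(trials), n_neuron)
  for (t in seq_len(nrow(trials))) {
    trial <- trials[t, ]
    segs <- trial_segments(trial, lead, tail_ms)
    rates <- segment_rates(pop, space, trial, segs)
    w0 <- trial[[align_event]] + window[1]
    w1 <- trial[[align_event]] + window[2]
    overlap <- pmax(0, pmin(segs$end, w1) - pmax(segs$start, w0)) / 1000
    lam[t, ] <- as.numeric(rates %*% overlap)
  }
  u <- outer(trials$trial_id, pop$neuron_id,
             function(tr, ne) {
               (vapply(seq_along(tr),
                       function(j) derive_seed(seed, ne[j], tr[j]),
                       integer(1)) + 0.5) / 2147483648
             })
  counts <- matrix(stats::qpois(u, lam), nrow(trials), n_neuron)
  colnames(counts) <- paste0("n", pop$neuron_id)
  dplyr::bind_cols(
    trials[, c("trial_id", "combo_id", "pos_id", "dir_id", "post_id")],
    tibble::as_tibble(counts)
  )
}
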