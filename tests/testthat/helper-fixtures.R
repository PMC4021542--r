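# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cache <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

fix_space <- function() cache("space", behavior_space())

fix_session <- function() {
  cache("session", simulate_task(fix_space(), n_blocks = 11, seed = 3))
}

# 20 well-tuned neurons recorded over a full session
fix_tuned <- function() {
  cache("tuned", {
    pop <- make_population(20, "tuned", seed = 2)
    spikes <- simulate_spikes(pop, fix_session(), seed = 5)
    list(pop = pop, spikes = spikes)
  })
}

# 20 untuned neurons (constant rates) over the same session
fix_untuned <- function() {
  cache("untuned", {
    pop <- make_population(20, "untuned", seed = 2)
    spikes <- simulate_spikes(pop, fix_session(), seed = 6)
    list(pop = pop, spikes = spikes)
  })
}

# A population with every epoch/tuning/gain knob flat, so each neuron fires
# at exactly its baseline rate everywhere.
flat_population <- function(baselines) {
  n <- length(baselines)
  make_population(n, "custom", neurons = tibble::tibble(
    neuron_id = seq_len(n), baseline = baselines, pref_deg = 0, kappa = 0,
    depth = 0, gain_x = 0, gain_y = 0,
    g_fixation = 1, g_visual = 1, g_memory = 1, g_perisaccadic = 1,
    g_postsaccadic1 = 1, g_postsaccadic2 = 1,
    peri_lead_ms = 80, peri_tail_ms = 100
  ))
}

# One trial with a hand-placed spike train on neuron 1, for window tests.
make_one_trial_spikes <- function(times_rel, align = "target_on") {
  trials <- simulate_task(fix_space(), n_blocks = 1, seed = 2)[1, ]
  attr(trials, "space") <- fix_space()
  spikes <- tibble::tibble(trial_id = trials$trial_id, neuron_id = 1L,
                           time_ms = trials[[align]] + times_rel)
  attr(spikes, "neuron_ids") <- 1L
  list(trials = trials, spikes = spikes)
}

# Minimal synthetic time-course object for epoch/onset tests.
fake_timecourse <- function(npc, step_ms = 10, behavior = "direction",
                            t0 = 0) {
  tc <- tibble::tibble(
    time = t0 + step_ms * (seq_along(npc) - 1),
    behavior = behavior, npc = npc, sem = 0, clipped = FALSE
  )
  attr(tc, "step_ms") <- step_ms
  class(tc) <- c("npc_timecourse", class(tc))
  tc
}

# Brute-force Bayes posterior: direct product of Poisson pmfs times the
# prior, normalized in probability space. Independent of the package's
# log-space implementation.
oracle_posterior_poisson <- function(r, mu, prior, floor_mu = 0.05) {
  lik <- apply(mu, 1, function(m) prod(dpois(r, pmax(m, floor_mu))))
  un <- lik * prior
  un / sum(un)
}

# Hand-unrolled leave-one-out decoding for a toy count table: for every
# trial, refit means and prior on the other trials and apply Bayes' rule
# term by term.
oracle_loo_posterior <- function(R, labels, n_behavior, floor_mu = 0.05) {
  n_t <- nrow(R)
  P <- matrix(NA_real_, n_t, n_behavior)
  for (t in seq_len(n_t)) {
    keep <- setdiff(seq_len(n_t), t)
    mu <- t(sapply(seq_len(n_behavior), function(b) {
      colMeans(R[keep[labels[keep] == b], , drop = FALSE])
    }))
    prior <- tabulate(labels[keep], nbins = n_behavior) / length(keep)
    P[t, ] <- oracle_posterior_poisson(R[t, ], mu, prior, floor_mu)
  }
  P
}
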