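rne_fixture <- function() {
  cache("rne_small", {
    sp <- fix_space()
    trials <- simulate_task(sp, n_blocks = 9, seed = 17)
    pop <- make_population(6, "tuned", depth_range = c(20, 35), seed = 4)
    spikes <- simulate_spikes(pop, trials, seed = 18)
    list(sp = sp, trials = trials, pop = pop, spikes = spikes)
  })
}

test_that("greedy elimination yields a nested, fully-covered, deterministic ranking", {
  fx <- rne_fixture()
  rk <- rne_rank(fx$spikes, fx$trials, fx$sp)
  n <- nrow(fx$pop)
  # the order is a permutation of the population
  expect_setequal(rk$order, fx$pop$neuron_id)
  # the objective curve is defined at every size from N down to 1
  expect_setequal(accuracy_vs_size(rk)$size, seq_len(n))
  # nestedness: the retained set at size k is the last k of the order
  expect_equal(rk$removed$size_after, (n - 1):1)
  # deterministic given identical inputs
  rk2 <- rne_rank(fx$spikes, fx$trials, fx$sp)
  expect_identical(rk$order, rk2$order)
  expect_identical(accuracy_vs_size(rk), accuracy_vs_size(rk2))
  # tidy: one row per neuron, least important first
  td <- tidy(rk)
  expect_equal(nrow(td), n)
  expect_equal(td$neuron_id, rk$order)
  expect_true(is.na(td$objective_after_removal[n]))
})

test_that("the recorded full-population objective matches an independent decode", {
  fx <- rne_fixture()
  rk <- rne_rank(fx$spikes, fx$trials, fx$sp)
  full <- accuracy_vs_size(rk)$objective[accuracy_vs_size(rk)$size == 6]
  # recompute the three epoch accuracies with the ordinary decoding surface
  acc_of <- function(align, window, truth_col, est_col) {
    counts <- window_counts(fx$spikes, fx$trials, align, window)
    dec <- loo_decode(counts, fx$sp, seed = 1)
    mean(tidy(npc_accuracy(dec[[truth_col]], dec[[est_col]], n_boot = 2,
                           seed = 1))$accuracy)
  }
  manual <- mean(c(
    acc_of("go_cue", c(-250, 0), "dir_id", "dir_est"),
    acc_of("target_on", c(-250, 0), "pos_id", "pos_est"),
    acc_of("fixation2_acquired", c(0, 250), "post_id", "post_est")
  ))
  expect_equal(full, manual, tolerance = 1e-10)
})

test_that("a single neuron ranks trivially and batch elimination visits stepped sizes", {
  fx <- rne_fixture()
  one <- dplyr::filter(tibble::as_tibble(fx$spikes), neuron_id == 1)
  attr(one, "neuron_ids") <- 1L
  rk1 <- rne_rank(one, fx$trials, fx$sp)
  expect_equal(rk1$order, 1L)
  expect_equal(nrow(rk1$removed), 0)

  rkb <- rne_rank(fx$spikes, fx$trials, fx$sp, batch = 2)
  expect_setequal(rkb$order, fx$pop$neuron_id)
  expect_equal(rkb$removed$size_after[c(2, 4)], c(4L, 2L))
})

test_that("sessions with too few trials per behavior are rejected", {
  sp <- fix_space()
  small <- simulate_task(sp, n_blocks = 3, seed = 2)
  fx <- rne_fixture()
  expect_error(rne_rank(fx$spikes, small, sp, min_trials = 9),
               class = "npc_invalid_input")
})

test_that("bias correction scales the epoch mean to the optimized reference and clips", {
  tc <- fake_timecourse(rep(0.3, 100))
  out <- bias_correct(tc, optimized = 0.6, behavior = "direction",
                      from = 0, to = 990)
  expect_equal(attr(out, "scale_factor"), 2)
  expect_equal(unique(out$npc), 0.6)
  # empirical = optimized -> identity
  id <- bias_correct(tc, optimized = 0.3, behavior = "direction",
                     from = 0, to = 990)
  expect_equal(id$npc, tc$npc)
  # scaled values never exceed 1
  hi <- bias_correct(fake_timecourse(c(rep(0.2, 50), rep(0.9, 50))),
                     optimized = 0.9, behavior = "direction",
                     from = 0, to = 990)
  expect_true(all(hi$npc <= 1))
  expect_error(bias_correct(fake_timecourse(rep(0, 50)), optimized = 0.5,
                            behavior = "direction", from = 0, to = 490),
               class = "npc_undefined_scaling")
  expect_error(bias_correct(tc, optimized = -1, behavior = "direction",
                            from = 0, to = 990),
               class = "npc_invalid_argument")
})
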