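test_that("population archetypes have the advertised structure", {
  untuned <- make_population(8, "untuned", seed = 1)
  expect_true(all(untuned$depth == 0))
  expect_true(all(untuned$gain_x == 0 & untuned$gain_y == 0))

  dup <- make_population(4, "duplicate-pair", seed = 1)
  cols <- setdiff(names(dup), "neuron_id")
  expect_identical(dup[1, cols], dup[2, cols])

  a <- make_population(325, "tuned", seed = 7)
  b <- make_population(325, "tuned", seed = 7)
  expect_identical(a, b)
  expect_true(all(a$pref_deg >= 0 & a$pref_deg < 360))
  expect_gt(diff(range(a$pref_deg)), 300)  # preferred directions tile the circle

  expect_error(make_population(3, "nonsense"), class = "npc_invalid_argument")
})

test_that("a flat-rate neuron produces Poisson counts with the nominal mean and variance", {
  sp <- fix_space()
  trials <- simulate_task(sp, n_blocks = 6, seed = 11)
  pop <- flat_population(c(20, 0))  # 20 spk/s and a silent neuron
  spikes <- simulate_spikes(pop, trials, seed = 13)
  expect_true(all(spikes$neuron_id == 1))  # rate 0 never fires
  counts <- window_counts(spikes, trials, "go_cue", c(-250, 0),
                          neuron_ids = 1:2)
  x <- counts$n1
  # rate x duration = 20 * 0.25 = 5 expected spikes; Poisson: mean = var
  expect_equal(mean(x), 5, tolerance = 0.1)
  expect_equal(var(x) / mean(x), 1, tolerance = 0.2)
  expect_true(all(counts$n2 == 0))
})

test_that("spike times stay inside the trial and respect the trial clock", {
  trials <- simulate_task(fix_space(), n_blocks = 1, seed = 2)
  fx <- fix_tuned()
  spikes <- simulate_spikes(fx$pop, trials, seed = 4)
  ends <- trials$trial_end[match(spikes$trial_id, trials$trial_id)]
  expect_true(all(spikes$time_ms >= 0 & spikes$time_ms <= ends))
})

test_that("per-(neuron, trial) streams: growing the population preserves existing trains", {
  trials <- simulate_task(fix_space(), n_blocks = 1, seed = 2)
  base <- make_population(3, "tuned", seed = 5)
  bigger <- make_population(5, "custom", neurons = dplyr::bind_rows(
    base, dplyr::mutate(make_population(2, "tuned", seed = 6),
                        neuron_id = 4:5)))
  s3 <- simulate_spikes(base, trials, seed = 9)
  s5 <- simulate_spikes(bigger, trials, seed = 9)
  expect_equal(
    dplyr::filter(tibble::as_tibble(s5), neuron_id <= 3),
    tibble::as_tibble(s3),
    ignore_attr = TRUE
  )
})

test_that("untuned populations are homogeneous across behaviors (chi-square screen)", {
  trials <- fix_session()
  fx <- fix_untuned()
  counts <- window_counts(fx$spikes, trials, "go_cue", c(-250, 0))
  m <- as.matrix(counts[, paste0("n", fx$pop$neuron_id)])
  pvals <- vapply(seq_len(ncol(m)), function(i) {
    per_combo <- rowsum(m[, i], counts$combo_id)
    suppressWarnings(stats::chisq.test(per_combo)$p.value)
  }, numeric(1))
  # at alpha = 0.01 at most a couple of 20 neurons should reject homogeneity
  expect_lte(sum(pvals < 0.01), 2)
})

test_that("direct count simulation matches the spike-train rate model", {
  trials <- fix_session()
  pop <- flat_population(c(12, 30))
  counts <- simulate_counts(pop, trials, "go_cue", c(-250, 0), seed = 21)
  expect_equal(mean(counts$n1), 3, tolerance = 0.1)
  expect_equal(mean(counts$n2), 7.5, tolerance = 0.1)
  expect_equal(var(counts$n1) / mean(counts$n1), 1, tolerance = 0.2)
  # reproducible and stream-stable under population growth
  again <- simulate_counts(pop, trials, "go_cue", c(-250, 0), seed = 21)
  expect_identical(counts, again)
  one <- simulate_counts(flat_population(12), trials, "go_cue", c(-250, 0),
                         seed = 21)
  expect_identical(one$n1, counts$n1)
})

test_that("fitted tuning converges to the generative means", {
  sp <- fix_space()
  trials <- fix_session()
  fx <- fix_tuned()
  counts <- window_counts(fx$spikes, trials, "go_cue", c(-250, 0))
  fit <- fit_tuning(counts, labels = counts$combo_id, model = "poisson")
  # Poisson SE of a combo mean is sqrt(mu / 11); 99%+ of cells within 4 SE
  se <- sqrt(pmax(fit$mu, 0.05) / 11)
  # reference: means from an independent much longer session
  long <- simulate_task(sp, n_blocks = 44, seed = 31)
  counts_long <- simulate_counts(fx$pop, long, "go_cue", c(-250, 0),
                                 seed = 33)
  fit_long <- fit_tuning(counts_long, labels = counts_long$combo_id)
  z <- abs(fit$mu - fit_long$mu) / (se + 1e-9)
  expect_gt(mean(z < 4), 0.99)
})
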