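test_that("causal boxcar counts cover [t - 250, t) and never look forward", {
  fx <- make_one_trial_spikes(c(-100, -50, 20))
  sc <- sliding_counts(fx$spikes, fx$trials, "target_on", 250, 10,
                       t_range = c(-250, 250))
  expect_equal(sc$n1[sc$time == 0], 2)     # spike at +20 excluded
  expect_equal(sc$n1[sc$time == 30], 3)    # now included
  expect_equal(sc$n1[sc$time == -60], 1)   # only the -100 spike in [-310, -60)
  # an empty spike train yields all-zero counts
  fx0 <- make_one_trial_spikes(numeric(0))
  sc0 <- sliding_counts(fx0$spikes, fx0$trials, "target_on", 250, 10,
                        t_range = c(-250, 250))
  expect_true(all(sc0$n1 == 0))
})

test_that("shifting all spikes by +delta shifts the count series by exactly +delta", {
  fx <- make_one_trial_spikes(c(-200, -120, -60, 35, 80, 140))
  sc <- sliding_counts(fx$spikes, fx$trials, "target_on", 250, 10,
                       t_range = c(-100, 100))
  shifted <- fx$spikes
  shifted$time_ms <- shifted$time_ms + 70
  sc2 <- sliding_counts(shifted, fx$trials, "target_on", 250, 10,
                        t_range = c(-100 + 70, 100 + 70))
  expect_equal(sc2$n1, sc$n1)
})

test_that("windows beyond the trial span are flagged as clipped", {
  fx <- make_one_trial_spikes(c(0, 10))
  sc <- sliding_counts(fx$spikes, fx$trials, "fixation_on", 250, 10,
                       t_range = c(0, 300))
  expect_true(all(sc$clipped[sc$time < 250]))   # window starts before t = 0
  expect_false(any(sc$clipped[sc$time >= 250 & sc$time <= 300]))
})

test_that("a homogeneous 20 spk/s train averages ~5 spikes per 250 ms window", {
  trials <- simulate_task(fix_space(), n_blocks = 3, seed = 12)
  pop <- flat_population(20)
  spikes <- simulate_spikes(pop, trials, seed = 14)
  sc <- sliding_counts(spikes, trials, "go_cue", 250, 50,
                       t_range = c(-500, 0))
  expect_equal(mean(sc$n1), 5, tolerance = 0.05)
})

test_that("epoch RMS has its closed forms and is step-size invariant for constants", {
  const <- fake_timecourse(rep(0.62, 100))
  expect_equal(epoch_rms(const, "direction", 0, 990)$rms, 0.62)
  const5 <- fake_timecourse(rep(0.62, 200), step_ms = 5)
  expect_equal(epoch_rms(const5, "direction", 0, 990)$rms, 0.62)
  half <- fake_timecourse(rep(c(0, 1), each = 50))
  expect_equal(epoch_rms(half, "direction", 0, 990)$rms, sqrt(0.5))
  expect_error(epoch_rms(const, "direction", 2000, 3000),
               class = "npc_invalid_argument")
})

test_that("onset and peak are recovered on constructed piecewise-linear signals", {
  # flat 0.1 then a ramp starting at t0 = 1000 ms
  ramp <- fake_timecourse(c(rep(0.1, 100), 0.1 + 0.004 * (1:100)))
  marks <- detect_onset_peak(ramp)
  expect_true(is.na(marks$reason))
  expect_lt(abs(marks$onset_ms - 1000), 20 + 1e-9)

  # symmetric triangular pulse peaks at the apex (t = 1000)
  tri <- fake_timecourse(c(rep(0.1, 50), 0.1 + 0.006 * (1:50),
                           0.1 + 0.006 * (49:0), rep(0.1, 51)))
  mt <- detect_onset_peak(tri)
  expect_lt(abs(mt$peak_ms - 1000), 20 + 1e-9)
  # onset precedes peak for a rise-then-fall signal
  expect_lt(mt$onset_ms, mt$peak_ms)
})

test_that("flat or structureless traces yield absent marks, not spurious detections", {
  flat <- fake_timecourse(rep(0.25, 150))
  mf <- detect_onset_peak(flat)
  expect_true(is.na(mf$onset_ms))
  expect_equal(mf$reason, "flat")

  # pure noise at zero signal: marks absent in >= 95% of seeds
  absent <- vapply(1:50, function(s) {
    set.seed(s)
    noise <- fake_timecourse(0.4 + rnorm(200, 0, 0.03))
    !is.na(detect_onset_peak(noise)$reason)
  }, logical(1))
  expect_gte(mean(absent), 0.95)
})

test_that("smoothing preserves the mean away from the edges", {
  set.seed(3)
  x <- 0.5 + 0.2 * sin(seq(0, 4 * pi, length.out = 300)) + rnorm(300, 0, 0.02)
  s <- npcdecode:::gauss_smooth(x, step_ms = 10)
  core <- 30:270
  expect_equal(mean(s[core]), mean(x[core]), tolerance = 0.005)
})

test_that("decoded time courses are flat at chance for untuned populations and rise for tuned ones", {
  sp <- fix_space()
  trials <- fix_session()
  tuned <- fix_tuned()
  tc <- npc_timecourse(tuned$spikes, trials, sp, "target_on",
                       t_range = c(-400, 900), step_ms = 50, n_boot = 100,
                       seed = 21)
  dir_pre <- tc$npc[tc$behavior == "direction" & tc$time <= 0]
  dir_mem <- tc$npc[tc$behavior == "direction" & tc$time >= 600]
  sem_mem <- tc$sem[tc$behavior == "direction" & tc$time >= 600]
  # at chance during fixation: direction info does not exist before the target
  expect_lt(max(abs(dir_pre - 1 / 8)), 0.08)
  # rises after target onset and stays elevated through the memory epoch
  expect_gt(min(dir_mem), max(dir_pre) + 3 * max(sem_mem))

  untuned <- fix_untuned()
  tcu <- npc_timecourse(untuned$spikes, trials, sp, "target_on",
                        t_range = c(-200, 600), step_ms = 50, n_boot = 100,
                        seed = 22)
  chance <- c(presaccade = 1 / 9, direction = 1 / 8, postsaccade = 1 / 25)
  for (b in names(chance)) {
    vals <- tcu$npc[tcu$behavior == b]
    expect_lt(max(abs(vals - chance[[b]])), 0.07)
  }
})
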