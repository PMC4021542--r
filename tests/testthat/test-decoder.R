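test_that("the prior is the relative occurrence frequency", {
  pr <- compute_prior(c("A", "A", "A", "B"))
  expect_equal(pr$prob[pr$behavior == "A"], 0.75)
  expect_equal(pr$prob[pr$behavior == "B"], 0.25)
  expect_error(compute_prior(integer(0)), class = "npc_invalid_argument")
  # a fully balanced session gives the uniform 1/72 prior over combos
  trials <- fix_session()
  pr72 <- compute_prior(trials$combo_id, behaviors = fix_space()$combos$combo_id)
  expect_equal(pr72$prob, rep(1 / 72, 72))
  # an unseen behavior gets zero mass
  pr0 <- compute_prior(c(1, 1), behaviors = 1:3)
  expect_equal(pr0$prob, c(1, 0, 0))
})

test_that("Bayes' rule: uniform cases, a hand-computed posterior, and normalization", {
  # equal likelihoods + uniform prior -> uniform posterior
  fit <- fit_tuning(matrix(2, 4, 1), labels = rep(1:2, 2))
  pr <- compute_prior(rep(1:2, 2))
  post <- posterior(2L, fit, pr)
  expect_equal(post$prob, c(0.5, 0.5))

  # 1 neuron, 2 behaviors, mu = (1, 2), uniform prior, r = 2:
  # p(b2) = 2 e^-2 / (e^-1 / 2 + 2 e^-2)
  fit <- fit_tuning(matrix(c(1, 1, 2, 2), 4, 1), labels = c(1, 1, 2, 2))
  post <- posterior(2L, fit, pr)
  expect_equal(post$prob[2], 2 * exp(-2) / (exp(-1) / 2 + 2 * exp(-2)),
               tolerance = 1e-12)

  # posteriors always normalize, across models and random populations
  set.seed(7)
  for (k in 1:20) {
    R <- matrix(rpois(60, 3), 12, 5)
    lab <- rep(1:3, 4)
    m <- if (k %% 2 == 0) "poisson" else "truncgauss"
    f <- fit_tuning(R, lab, model = m)
    p <- posterior(R[1, ], f, compute_prior(lab))
    expect_equal(sum(p$prob), 1, tolerance = 1e-9)
    expect_true(all(p$prob >= 0))
    expect_true(is.finite(attr(p, "log_evidence")))
  }
})

test_that("MAP estimation takes the argmax and breaks exact ties uniformly", {
  post <- tibble::tibble(behavior = 1:3, prob = c(0.7, 0.2, 0.1))
  expect_equal(map_estimate(post), 1)
  tied <- tibble::tibble(behavior = 1:2, prob = c(0.5, 0.5))
  picks <- vapply(1:400, function(s) map_estimate(tied, seed = s), numeric(1))
  expect_gt(mean(picks == 1), 0.4)
  expect_lt(mean(picks == 1), 0.6)
  # the same seed always resolves a tie the same way
  expect_equal(map_estimate(tied, seed = 5), map_estimate(tied, seed = 5))
})

test_that("postsaccade marginalization sums combos onto landing nodes and conserves mass", {
  sp <- fix_space()
  uniform <- structure(
    tibble::tibble(behavior = sp$combos$combo_id, prob = rep(1 / 72, 72)),
    class = c("npc_posterior", class(tibble::tibble())))
  m <- marginalize_postsaccade(uniform, sp)
  expect_equal(sum(m$prob), 1, tolerance = 1e-12)
  center <- sp$postsaccade$post_id[sp$postsaccade$x == 0 &
                                     sp$postsaccade$y == 0]
  expect_equal(m$prob[m$behavior == center], 8 / 72, tolerance = 1e-12)
  corners <- sp$postsaccade$post_id[abs(sp$postsaccade$x) == 16 &
                                      abs(sp$postsaccade$y) == 16]
  expect_equal(m$prob[m$behavior %in% corners], rep(1 / 72, 4),
               tolerance = 1e-12)

  # a point mass maps to the composed landing node
  point <- uniform
  point$prob <- as.numeric(point$behavior == 5)
  mp <- marginalize_postsaccade(point, sp)
  expect_equal(mp$prob[mp$behavior == sp$combos$post_id[5]], 1)

  short <- uniform[1:10, ]
  expect_error(marginalize_postsaccade(short, sp),
               class = "npc_invalid_argument")
})

test_that("leave-one-out decoding matches a hand-unrolled oracle on a toy session", {
  sp1 <- behavior_space(extent = 1)  # 1 position, 8 combos
  trials <- simulate_task(sp1, n_blocks = 3, seed = 8)
  set.seed(15)
  R <- matrix(rpois(nrow(trials) * 2, lambda = rep(c(2, 6), each = nrow(trials))),
              ncol = 2)
  counts <- dplyr::bind_cols(
    trials[, c("trial_id", "combo_id", "pos_id", "dir_id", "post_id")],
    tibble::tibble(n1 = R[, 1], n2 = R[, 2]))
  dec <- loo_decode(counts, sp1, "poisson", seed = 1)
  lab <- match(counts$combo_id, sp1$combos$combo_id)
  P_oracle <- oracle_loo_posterior(R, lab, 8)
  p_dir_oracle <- P_oracle %*% npcdecode:::marginalization_matrix(sp1, "direction")
  expect_equal(dec$p_true_dir,
               p_dir_oracle[cbind(seq_len(nrow(R)), counts$dir_id)],
               tolerance = 1e-10)
})

test_that("noiseless, well-separated responses decode perfectly, and more neurons never hurt", {
  sp1 <- behavior_space(extent = 1)
  trials <- simulate_task(sp1, n_blocks = 2, seed = 8)
  # counts equal to widely separated means, exactly, for every trial
  mu_of <- function(d) 20 * d
  base <- tibble::tibble(n1 = mu_of(trials$dir_id))
  mk <- function(extra) {
    dplyr::bind_cols(
      trials[, c("trial_id", "combo_id", "pos_id", "dir_id", "post_id")],
      base, extra)
  }
  d1 <- loo_decode(mk(NULL), sp1, seed = 2)
  expect_equal(mean(d1$dir_est == d1$dir_id), 1)
  expect_equal(mean(d1$post_est == d1$post_id), 1)
  # add a second informative neuron: still perfect
  d2 <- loo_decode(mk(tibble::tibble(n2 = 180 - mu_of(trials$dir_id))),
                   sp1, seed = 2)
  expect_equal(mean(d2$dir_est == d2$dir_id), 1)
})

test_that("accuracy aggregates per behavior, and the bootstrap SEM matches the binomial law", {
  r <- npc_accuracy(c(1, 1, 2, 2), c(1, 1, 2, 1), n_boot = 50, seed = 1)
  expect_equal(r$npc, 0.75)  # unweighted mean of 1.0 and 0.5
  expect_equal(tidy(r)$accuracy, c(1, 0.5))
  expect_equal(glance(r)$n_trials, 4)

  all_ok <- npc_accuracy(1:5, 1:5, n_boot = 50, seed = 1)
  expect_equal(all_ok$npc, 1)
  expect_equal(all_ok$sem, 0)

  # one behavior, Bernoulli(1/2) agreement: SEM ~ sqrt(0.25 / n)
  set.seed(99)
  n <- 400
  est <- rbinom(n, 1, 0.5)
  r1 <- npc_accuracy(rep(1, n), ifelse(est == 1, 1, 2), n_boot = 1000,
                     seed = 3)
  expect_equal(r1$sem, sqrt(0.25 / n), tolerance = 0.15)
  expect_error(npc_accuracy(numeric(0), numeric(0)),
               class = "npc_invalid_argument")
})

test_that("marginal-mode decoding fits position and direction separately and stays consistent", {
  sp <- fix_space()
  trials <- fix_session()
  fx <- fix_tuned()
  counts <- window_counts(fx$spikes, trials, "go_cue", c(-250, 0))
  dj <- loo_decode(counts, sp, mode = "joint", seed = 4)
  dm <- loo_decode(counts, sp, mode = "marginal", seed = 4)
  # both modes find the strong memory-epoch direction signal
  expect_gt(mean(dj$dir_est == dj$dir_id), 0.6)
  expect_gt(mean(dm$dir_est == dm$dir_id), 0.6)
  # posterior of the truth is a proper probability in both
  for (d in list(dj, dm)) {
    expect_true(all(d$p_true_dir >= 0 & d$p_true_dir <= 1 + 1e-12))
    expect_true(all(d$p_true_post >= 0 & d$p_true_post <= 1 + 1e-12))
  }
})
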