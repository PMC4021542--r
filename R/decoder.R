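# Bayesian decoding: priors, posteriors, MAP estimates under leave-one-out
# cross-validation, and the postsaccade marginalization.

#' Empirical behavior prior
#'
#' The prior probability of each behavior is its relative frequency among the
#' trials (the task has no error trials, so occurrence counts define the
#' behavioral history). Behaviors listed in `behaviors` but absent from
#' `labels` get probability 0.
#'
#' @param labels Behavior label per trial.
#' @param behaviors Optional full behavior set.
#' @return An `npc_prior` tibble with columns `behavior`, `prob`.
#' @export
compute_prior <- function(labels, behaviors = NULL) {
  if (length(labels) == 0) {
    abort("`labels` must contain at least one trial.",
          class = "npc_invalid_argument")
  }
  behaviors <- behaviors %||% sort(unique(labels))
  n <- tabulate(match(labels, behaviors), nbins = length(behaviors))
  out <- tibble::tibble(behavior = behaviors, prob = n / length(labels))
  class(out) <- c("npc_prior", class(out))
  out
}

#' Posterior over behaviors for one population response
#'
#' Bayes' rule: the posterior `p(b | r)` is proportional to the population
#' likelihood `p(r | b)` times the prior `p(b)`, normalized by the evidence
#' `p(r)`. Computed in log space with a log-sum-exp normalizer.
#'
#' @param r Integer count vector, one entry per neuron.
#' @param model A [fit_tuning()] model.
#' @param prior An [compute_prior()] prior over the model's behavior set.
#' @param floor_mu,floor_sigma2 Parameter floors (see [population_loglik()]).
#' @return An `npc_posterior` tibble (`behavior`, `prob`) with attribute
#'   `log_evidence` = log p(r) (up to the count-only constant dropped from
#'   the Poisson likelihood).
#' @export
posterior <- function(r, model, prior,
                      floor_mu = floor_mu_default,
                      floor_sigma2 = floor_sigma2_default) {
  stopifnot(inherits(model, "tuning_model"))
  pb <- prior$prob[match(model$behaviors, prior$behavior)]
  if (any(is.na(pb))) {
    abort("`prior` must cover the model's behavior set.",
          class = "npc_invalid_argument")
  }
  if (all(pb == 0)) {
    abort("Prior puts no mass on the behavior set.",
          class = "npc_invalid_state")
  }
  ll <- vapply(model$behaviors, function(b) {
    population_loglik(r, model, b, floor_mu, floor_sigma2)
  }, numeric(1))
  lp <- ll + log(pb)
  lse <- max(lp) + log(sum(exp(lp - max(lp))))
  out <- tibble::tibble(behavior = model$behaviors, prob = exp(lp - lse))
  attr(out, "log_evidence") <- lse
  class(out) <- c("npc_posterior", class(out))
  out
}

#' Maximum a posteriori estimate
#'
#' Returns the behavior maximizing the posterior. Exact ties are broken
#' uniformly at random from a seeded stream so tied decisions are
#' reproducible but unbiased.
#'
#' @param post An `npc_posterior` (or any tibble with `behavior`, `prob`).
#' @param seed Integer seed for tie-breaking.
#' @param tol Absolute probability tolerance within which the maximum is
#'   considered tied.
#' @export
map_estimate <- function(post, seed = 1, tol = 1e-12) {
  p <- post$prob
  cand <- which(p >= max(p) - tol)
  if (length(cand) == 1) {
    return(post$behavior[cand])
  }
  with_seed(derive_seed(seed, 777L), post$behavior[sample(cand, 1)])
}

#' Marginalize a joint posterior onto postsaccade eye positions
#'
#' The postsaccade eye position is the vector sum of the presaccade position
#' and the saccade displacement, so several (position, direction)
#' combinations can land on the same node. The posterior of a postsaccade
#' position is the sum of the joint posteriors of all combinations that
#' compose to it; total mass is conserved exactly.
#'
#' @param joint_post An `npc_posterior` over the 72 combos (`behavior` =
#'   `combo_id`).
#' @param space The [behavior_space()].
#' @return An `npc_posterior` over `post_id`.
#' @export
marginalize_postsaccade <- function(joint_post, space) {
  stopifnot(inherits(space, "behavior_space"))
  if (!setequal(joint_post$behavior, space$combos$combo_id)) {
    abort("`joint_post` must cover exactly the combo set of `space`.",
          class = "npc_invalid_argument")
  }
  idx <- match(joint_post$behavior, space$combos$combo_id)
  post_id <- space$combos$post_id[idx]
  agg <- rowsum(joint_post$prob, post_id)
  out <- tibble::tibble(
    behavior = as.integer(rownames(agg)),
    prob = as.numeric(agg)
  ) |> dplyr::arrange(.data$behavior)
  class(out) <- c("npc_posterior", class(out))
  out
}

# ---- vectorized LOO posterior core -----------------------------------------

# Leave-one-out posterior matrix (trials x behaviors). For each trial the
# tuning parameters (and, for prior_mode = "loo", the prior) are refit on all
# other trials. Only the held-out trial's own-behavior column differs from
# the full fit, which keeps the computation O(trials x neurons).
# Count-only constants are dropped (they cancel in the normalization).
loo_posterior_matrix <- function(R, labels, n_behavior,
                                 model = c("poisson", "truncgauss"),
                                 prior_mode = c("loo", "full"),
                                 floor_mu = floor_mu_default,
                                 floor_sigma2 = floor_sigma2_default) {
  model <- match.arg(model)
  prior_mode <- match.arg(prior_mode)
  n_t <- nrow(R)
  g <- factor(labels, levels = seq_len(n_behavior))
  n_b <- tabulate(g, nbins = n_behavior)
  min_n <- if (model == "truncgauss") 3 else 2
  if (any(n_b < min_n)) {
    bad <- which(n_b < min_n)
    abort(sprintf(
      "Behavior(s) %s need at least %d trials for leave-one-out decoding.",
      paste(bad, collapse = ", "), min_n),
      class = "npc_unfittable_behavior")
  }
  S <- rowsum(R, g)  # B x N sums

  if (model == "poisson") {
    mu_f <- pmax(S / n_b, floor_mu)
    LL <- R %*% t(log(mu_f)) -
      matrix(rowSums(mu_f), n_t, n_behavior, byrow = TRUE)
    for (b in seq_len(n_behavior)) {
      idx <- which(labels == b)
      m_loo <- (matrix(S[b, ], length(idx), ncol(R), byrow = TRUE) - R[idx, ,
                drop = FALSE]) / (n_b[b] - 1)
      m_loo <- pmax(m_loo, floor_mu)
      LL[idx, b] <- rowSums(R[idx, , drop = FALSE] * log(m_loo)) -
        rowSums(m_loo)
    }
  } else {
    Q <- rowsum(R^2, g)
    mu <- S / n_b
    s2 <- (Q - n_b * mu^2) / (n_b - 1)
    mu_f <- pmax(mu, floor_mu)
    s2_f <- pmax(s2, floor_sigma2)
    tailterm <- matrix(
      pnorm(0, mu_f, sqrt(s2_f), lower.tail = FALSE, log.p = TRUE),
      n_behavior, ncol(R))
    const_b <- rowSums(mu_f^2 / (2 * s2_f) + 0.5 * log(2 * pi * s2_f) +
                         tailterm)
    LL <- -(R^2 %*% t(1 / (2 * s2_f))) + R %*% t(mu_f / s2_f) -
      matrix(const_b, n_t, n_behavior, byrow = TRUE)
    for (b in seq_len(n_behavior)) {
      idx <- which(labels == b)
      nb <- n_b[b]
      Rb <- R[idx, , drop = FALSE]
      m_loo <- (matrix(S[b, ], length(idx), ncol(R), byrow = TRUE) - Rb) /
        (nb - 1)
      v_loo <- (matrix(Q[b, ], length(idx), ncol(R), byrow = TRUE) - Rb^2 -
                  (nb - 1) * m_loo^2) / (nb - 2)
      m_loo <- pmax(m_loo, floor_mu)
      v_loo <- pmax(v_loo, floor_sigma2)
      s_loo <- sqrt(v_loo)
      LL[idx, b] <- rowSums(
        dnorm(Rb, m_loo, s_loo, log = TRUE) -
          pnorm(0, m_loo, s_loo, lower.tail = FALSE, log.p = TRUE))
    }
  }

  if (prior_mode == "full") {
    lp <- log(n_b / n_t)
    LP <- LL + matrix(lp, n_t, n_behavior, byrow = TRUE)
  } else {
    lp <- log(n_b)  # the -log(n_t - 1) constant cancels in normalization
    LP <- LL + matrix(lp, n_t, n_behavior, byrow = TRUE)
    own <- cbind(seq_len(n_t), labels)
    LP[own] <- LP[own] - log(n_b[labels]) + log(n_b[labels] - 1)
  }

  mx <- apply(LP, 1, max)
  P <- exp(LP - mx)
  P / rowSums(P)
}

# Row-wise MAP with seeded uniform tie-breaking. Returns integer indices.
map_rows <- function(P, seed, tol = 1e-12) {
  mx <- apply(P, 1, max)
  est <- max.col(P, ties.method = "first")
  n_cand <- rowSums(P >= mx - tol)
  tied <- which(n_cand > 1)
  if (length(tied) > 0) {
    with_seed(derive_seed(seed, 777L), {
      for (t in tied) {
        cand <- which(P[t, ] >= mx[t] - tol)
        est[t] <- cand[sample.int(length(cand), 1)]
      }
    })
  }
  est
}

#' Decode a session by leave-one-out MAP inference
#'
#' For each trial, tuning curves (and the prior, when `prior_mode = "loo"`)
#' are refit on all other trials; the posterior over behaviors is evaluated
#' for the held-out response; and the MAP estimate is recorded for each of
#' the three oculomotor behaviors: presaccade eye position, saccade
#' direction, and postsaccade eye position.
#'
#' With `mode = "joint"` (default) a single posterior over the 72
#' (position, direction) combinations is computed; the presaccade and
#' direction posteriors are its marginals, and the postsaccade posterior sums
#' the joint posterior over all combinations composing to each landing node.
#' With `mode = "marginal"` the position and direction models are fit
#' separately (tuning per 9 positions and per 8 directions), and the
#' postsaccade posterior composes the two independent posteriors.
#'
#' @param counts A count table ([window_counts()] / [simulate_counts()]).
#' @param space The [behavior_space()]; defaults to the standard 3 x 3 grid.
#' @param model `"poisson"` or `"truncgauss"`.
#' @param prior_mode `"loo"` (prior refit per fold) or `"full"`.
#' @param mode `"joint"` or `"marginal"`.
#' @param floor_mu,floor_sigma2 Likelihood parameter floors.
#' @param seed Seed for MAP tie-breaking.
#' @return An `npc_decode` tibble, one row per trial, with true and estimated
#'   ids for the three behaviors (`pos_id`/`pos_est`, `dir_id`/`dir_est`,
#'   `post_id`/`post_est`) and the posterior probability assigned to each
#'   true behavior (`p_true_pos`, `p_true_dir`, `p_true_post`).
#' @export
loo_decode <- function(counts, space = behavior_space(),
                       model = c("poisson", "truncgauss"),
                       prior_mode = c("loo", "full"),
                       mode = c("joint", "marginal"),
                       floor_mu = floor_mu_default,
                       floor_sigma2 = floor_sigma2_default,
                       seed = 1) {
  model <- match.arg(model)
  prior_mode <- match.arg(prior_mode)
  mode <- match.arg(mode)
  R <- count_matrix(counts)
  n_t <- nrow(R)

  if (mode == "joint") {
    lab <- match(counts$combo_id, space$combos$combo_id)
    P <- loo_posterior_matrix(R, lab, nrow(space$combos), model, prior_mode,
                              floor_mu, floor_sigma2)
    P_pos <- P %*% marginalization_matrix(space, "presaccade")
    P_dir <- P %*% marginalization_matrix(space, "direction")
    P_post <- P %*% marginalization_matrix(space, "postsaccade")
  } else {
    lab_pos <- match(counts$pos_id, space$positions$pos_id)
    lab_dir <- match(counts$dir_id, space$directions$dir_id)
    P_pos <- loo_posterior_matrix(R, lab_pos, nrow(space$positions), model,
                                  prior_mode, floor_mu, floor_sigma2)
    P_dir <- loo_posterior_matrix(R, lab_dir, nrow(space$directions), model,
                                  prior_mode, floor_mu, floor_sigma2)
    # independent posteriors composed onto the postsaccade grid
    P_joint <- matrix(0, n_t, nrow(space$combos))
    for (k in seq_len(nrow(space$combos))) {
      P_joint[, k] <- P_pos[, space$combos$pos_id[k]] *
        P_dir[, space$combos$dir_id[k]]
    }
    P_post <- P_joint %*% marginalization_matrix(space, "postsaccade")
  }

  out <- tibble::tibble(
    trial_id = counts$trial_id,
    pos_id = counts$pos_id,
    dir_id = counts$dir_id,
    post_id = counts$post_id,
    pos_est = space$positions$pos_id[map_rows(P_pos, derive_seed(seed, 1L))],
    dir_est = space$directions$dir_id[map_rows(P_dir, derive_seed(seed, 2L))],
    post_est = space$postsaccade$post_id[map_rows(P_post,
                                                  derive_seed(seed, 3L))],
    p_true_pos = P_pos[cbind(seq_len(n_t),
                             match(counts$pos_id, space$positions$pos_id))],
    p_true_dir = P_dir[cbind(seq_len(n_t),
                             match(counts$dir_id, space$directions$dir_id))],
    p_true_post = P_post[cbind(seq_len(n_t),
                               match(counts$post_id,
                                     space$postsaccade$post_id))]
  )
  attr(out, "model") <- model
  attr(out, "mode") <- mode
  attr(out, "prior_mode") <- prior_mode
  class(out) <- c("npc_decode", class(out))
  out
}
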