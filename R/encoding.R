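# Encoding model: empirical tuning curves and parametric spike-count
# likelihoods (Poisson, truncated Gaussian), evaluated in log space.

#' Fit empirical tuning curves
#'
#' Estimates each neuron's tuning curve mu(b) — the mean spike count per
#' behavior — from training trials, and for the truncated-Gaussian model also
#' the unbiased (n - 1) sample variance sigma2(b).
#'
#' @param counts A count table (see [window_counts()]) or a numeric
#'   trials x neurons matrix.
#' @param labels Behavior label per trial (integer ids).
#' @param model `"poisson"` (mean only) or `"truncgauss"` (mean + variance).
#' @param behaviors The full behavior set the model is fit over; defaults to
#'   the labels present. A behavior with no training trial (or fewer than two
#'   for `"truncgauss"`) raises an `npc_unfittable_behavior` error naming it.
#' @return A `tuning_model`: list with `mu` (behaviors x neurons matrix),
#'   `sigma2` (same shape, `"truncgauss"` only), `model`, `behaviors`,
#'   `n_per_behavior`.
#' @examples
#' fit_tuning(matrix(c(3, 5), 2, 1), labels = c(1, 1))$mu  # mean 4
#' @export
fit_tuning <- function(counts, labels, model = c("poisson", "truncgauss"),
                       behaviors = NULL) {
  model <- match.arg(model)
  m <- if (is.matrix(counts)) counts else count_matrix(counts)
  if (nrow(m) != length(labels)) {
    abort("`labels` must have one entry per trial.",
          class = "npc_invalid_argument")
  }
  behaviors <- behaviors %||% sort(unique(labels))
  n_b <- tabulate(match(labels, behaviors), nbins = length(behaviors))
  min_n <- if (model == "truncgauss") 2 else 1
  if (any(n_b < min_n)) {
    bad <- behaviors[n_b < min_n]
    abort(sprintf("Behavior(s) %s have fewer than %d training trial(s).",
                  paste(bad, collapse = ", "), min_n),
          class = "npc_unfittable_behavior")
  }
  g <- factor(labels, levels = behaviors)
  s <- rowsum(m, g)
  mu <- s / n_b
  sigma2 <- NULL
  if (model == "truncgauss") {
    q <- rowsum(m^2, g)
    sigma2 <- (q - n_b * mu^2) / (n_b - 1)
    sigma2[sigma2 < 0] <- 0  # guard tiny negative rounding residue
    sigma2 <- unname(as.matrix(sigma2))
  }
  structure(list(mu = unname(as.matrix(mu)), sigma2 = sigma2, model = model,
                 behaviors = behaviors, n_per_behavior = n_b),
            class = "tuning_model")
}

check_counts_arg <- function(r) {
  if (any(r < 0) || any(r != floor(r))) {
    abort("Spike counts must be non-negative integers.",
          class = "npc_invalid_argument")
  }
}

#' Poisson spike-count likelihood
#'
#' Probability of observing `r` spikes under a Poisson model with mean
#' `mu`: `mu^r / r! * exp(-mu)`. Vectorized; `mu = 0` follows the `0^0 = 1`
#' convention (a silent neuron observes 0 spikes with probability 1).
#'
#' @param r Non-negative integer count(s).
#' @param mu Mean count(s), `>= 0`.
#' @param log Return the log likelihood?
#' @export
poisson_likelihood <- function(r, mu, log = FALSE) {
  check_counts_arg(r)
  if (any(mu < 0)) {
    abort("`mu` must be >= 0.", class = "npc_invalid_argument")
  }
  dpois(r, mu, log = log)
}

#' Truncated-Gaussian spike-count likelihood
#'
#' Gaussian density with mean `mu` and variance `sigma2`, renormalized by its
#' integral over the positive half-line (so the truncated density at counts
#' near zero is inflated by the truncated mass), evaluated at integer `r`.
#' The normalizer is the continuous upper-tail integral, computed in closed
#' form from the Gaussian tail function.
#'
#' @param r Non-negative count(s).
#' @param mu Mean(s).
#' @param sigma2 Variance(s), `> 0`.
#' @param log Return the log density?
#' @export
truncgauss_likelihood <- function(r, mu, sigma2, log = FALSE) {
  if (any(r < 0)) {
    abort("`r` must be >= 0.", class = "npc_invalid_argument")
  }
  if (any(sigma2 <= 0)) {
    abort("`sigma2` must be > 0.", class = "npc_invalid_state")
  }
  s <- sqrt(sigma2)
  ll <- dnorm(r, mu, s, log = TRUE) -
    pnorm(0, mu, s, lower.tail = FALSE, log.p = TRUE)
  if (log) ll else exp(ll)
}

# Floor parameters before likelihood evaluation so behaviors whose training
# counts were all zero never produce zero-probability likelihoods.
floor_mu_default <- 0.05
floor_sigma2_default <- 0.25

#' Population log likelihood of a count vector
#'
#' Log probability of the population response `r` (one count per neuron)
#' given behavior `b`, under independence: the sum across neurons of the
#' single-neuron log likelihoods. Means are floored at `floor_mu` (and
#' variances at `floor_sigma2`) so the result is always finite.
#'
#' @param r Integer vector of counts, one per neuron.
#' @param model A [fit_tuning()] model.
#' @param b Behavior (must be in `model$behaviors`).
#' @param floor_mu,floor_sigma2 Parameter floors applied before evaluation.
#' @return A single log probability.
#' @export
population_loglik <- function(r, model, b,
                              floor_mu = floor_mu_default,
                              floor_sigma2 = floor_sigma2_default) {
  stopifnot(inherits(model, "tuning_model"))
  if (length(r) != ncol(model$mu)) {
    abort("`r` must have one count per neuron in the model.",
          class = "npc_invalid_argument")
  }
  bi <- match(b, model$behaviors)
  if (is.na(bi)) {
    abort("`b` is not in the model's behavior set.",
          class = "npc_invalid_argument")
  }
  mu <- pmax(model$mu[bi, ], floor_mu)
  if (model$model == "poisson") {
    check_counts_arg(r)
    sum(dpois(r, mu, log = TRUE))
  } else {
    s2 <- pmax(model$sigma2[bi, ], floor_sigma2)
    sum(truncgauss_likelihood(r, mu, s2, log = TRUE))
  }
}
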