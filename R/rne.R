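# Recursive Neuronal Elimination: greedy backward elimination of the neuron
# whose removal best preserves (maximizes) the remaining population's
# decoding accuracy, averaged across the three oculomotor behaviors.

#' Objective specification for Recursive Neuronal Elimination
#'
#' The RNE objective is the decoding accuracy averaged across the three
#' behaviors, each evaluated (root mean square over the listed causal-window
#' end points) in the epoch that best mediates it: the memory epoch for
#' saccade direction, the fixation epoch for presaccade eye position, and
#' fixation II for postsaccade eye position. The default evaluates one
#' 250 ms window per epoch (the RMS of a single point is the point), which
#' keeps the candidate-removal loop affordable; supply more window ends per
#' epoch for a denser epoch RMS.
#'
#' @param window_ms Counting window length.
#' @param direction_ends,presaccade_ends,postsaccade_ends Window end times
#'   (ms, relative to each behavior's alignment event) evaluated for the
#'   epoch RMS.
#' @return A list of per-behavior specs (`behavior`, `align_event`,
#'   `window_ms`, `ends`).
#' @export
rne_objective <- function(window_ms = 250,
                          direction_ends = 0,
                          presaccade_ends = 0,
                          postsaccade_ends = 250) {
  list(
    list(behavior = "direction", align_event = "go_cue",
         window_ms = window_ms, ends = direction_ends),
    list(behavior = "presaccade", align_event = "target_on",
         window_ms = window_ms, ends = presaccade_ends),
    list(behavior = "postsaccade", align_event = "fixation2_acquired",
         window_ms = window_ms, ends = postsaccade_ends)
  )
}

# Per-neuron additive log-likelihood components for the LOO posterior:
# A[, , i] is neuron i's contribution to the trials x behaviors LOO
# log-likelihood (own-behavior column already leave-one-out corrected).
# Summing over any neuron subset gives that subset's population loglik.
per_neuron_components <- function(R, labels, n_behavior, model,
                                  floor_mu = floor_mu_default,
                                  floor_sigma2 = floor_sigma2_default) {
  n_t <- nrow(R)
  n_n <- ncol(R)
  g <- factor(labels, levels = seq_len(n_behavior))
  n_b <- tabulate(g, nbins = n_behavior)
  S <- rowsum(R, g)
  A <- array(0, c(n_t, n_behavior, n_n))
  if (model == "poisson") {
    mu_f <- pmax(S / n_b, floor_mu)
    for (i in seq_len(n_n)) {
      A[, , i] <- outer(R[, i], log(mu_f[, i])) -
        matrix(mu_f[, i], n_t, n_behavior, byrow = TRUE)
    }
    for (b in seq_len(n_behavior)) {
      idx <- which(labels == b)
      m_loo <- pmax((matrix(S[b, ], length(idx), n_n, byrow = TRUE) -
                       R[idx, , drop = FALSE]) / (n_b[b] - 1), floor_mu)
      corr <- R[idx, , drop = FALSE] * log(m_loo) - m_loo
      for (i in seq_len(n_n)) A[idx, b, i] <- corr[, i]
    }
  } else {
    Q <- rowsum(R^2, g)
    mu <- S / n_b
    s2 <- (Q - n_b * mu^2) / (n_b - 1)
    mu_f <- pmax(mu, floor_mu)
    s2_f <- pmax(s2, floor_sigma2)
    for (i in seq_len(n_n)) {
      tailt <- pnorm(0, mu_f[, i], sqrt(s2_f[, i]), lower.tail = FALSE,
                     log.p = TRUE)
      const <- mu_f[, i]^2 / (2 * s2_f[, i]) + 0.5 * log(2 * pi * s2_f[, i]) +
        tailt
      A[, , i] <- -outer(R[, i]^2, 1 / (2 * s2_f[, i])) +
        outer(R[, i], mu_f[, i] / s2_f[, i]) -
        matrix(const, n_t, n_behavior, byrow = TRUE)
    }
    for (b in seq_len(n_behavior)) {
      idx <- which(labels == b)
      nb <- n_b[b]
      Rb <- R[idx, , drop = FALSE]
      m_loo <- (matrix(S[b, ], length(idx), n_n, byrow = TRUE) - Rb) / (nb - 1)
      v_loo <- (matrix(Q[b, ], length(idx), n_n, byrow = TRUE) - Rb^2 -
                  (nb - 1) * m_loo^2) / (nb - 2)
      m_loo <- pmax(m_loo, floor_mu)
      v_loo <- pmax(v_loo, floor_sigma2)
      corr <- dnorm(Rb, m_loo, sqrt(v_loo), log = TRUE) -
        pnorm(0, m_loo, sqrt(v_loo), lower.tail = FALSE, log.p = TRUE)
      for (i in seq_len(n_n)) A[idx, b, i] <- corr[, i]
    }
  }
  list(A = A, n_b = n_b)
}

# Accuracy (unweighted mean of per-behavior fractions correct) of the MAP
# estimate of one behavior variable, from a trials x combos LOO loglik.
window_accuracy <- function(LL, n_b, labels, marg, truth, prior_mode) {
  n_t <- nrow(LL)
  if (prior_mode == "full") {
    LP <- LL + matrix(log(n_b / n_t), n_t, ncol(LL), byrow = TRUE)
  } else {
    LP <- LL + matrix(log(n_b), n_t, ncol(LL), byrow = TRUE)
    own <- cbind(seq_len(n_t), labels)
    LP[own] <- LP[own] - log(n_b[labels]) + log(n_b[labels] - 1)
  }
  P <- exp(LP - apply(LP, 1, max))
  est <- max.col(P %*% marg, ties.method = "first")
  correct <- est == truth
  acc <- as.numeric(rowsum(as.numeric(correct), truth)) /
    tabulate(truth, nbins = ncol(marg))[sort(unique(truth))]
  mean(acc)
}

#' Rank neurons by Recursive Neuronal Elimination
#'
#' Iteratively removes the neuron whose removal maximizes the decoding
#' accuracy of the remaining population (objective ties broken toward the
#' lower neuron id), producing a ranking from least to most important and
#' the objective value at every population size. The objective is the
#' accuracy averaged across the three behaviors, each summarized in its
#' mediating epoch (see [rne_objective()]); decoding is leave-one-out MAP
#' inference on the joint combo posterior, as in [loo_decode()].
#'
#' Sessions are expected to provide at least `min_trials` trials per
#' oculomotor behavior (a balanced session from [simulate_task()] with
#' `n_blocks >= min_trials` satisfies this); sessions below the floor are
#' rejected.
#'
#' @param spikes Spike tibble.
#' @param trials Trial table.
#' @param space The [behavior_space()].
#' @param model `"poisson"` or `"truncgauss"`.
#' @param prior_mode `"loo"` or `"full"`.
#' @param objective An [rne_objective()] specification.
#' @param batch Neurons removed per iteration (default 1; with `batch > 1`
#'   the k jointly-least-important by single-removal score are removed and
#'   the objective curve is only defined at the visited sizes).
#' @param min_trials Minimum trials per behavior (default 9).
#' @param floor_mu,floor_sigma2 Likelihood floors.
#' @return An `rne_ranking`: list with `order` (neuron ids from least to
#'   most important; the last element is the most important), `removed`
#'   (tibble: `step`, `neuron_id`, `size_after`, `objective`),
#'   `accuracy_at_size` (tibble: `size`, `objective`), and `objective_spec`.
#' @export
rne_rank <- function(spikes, trials, space = behavior_space(),
                     model = c("poisson", "truncgauss"),
                     prior_mode = c("loo", "full"),
                     objective = rne_objective(), batch = 1,
                     min_trials = 9,
                     floor_mu = floor_mu_default,
                     floor_sigma2 = floor_sigma2_default) {
  model <- match.arg(model)
  prior_mode <- match.arg(prior_mode)
  check_trials(trials)
  per_combo <- tabulate(match(trials$combo_id, space$combos$combo_id),
                        nbins = nrow(space$combos))
  if (any(per_combo < min_trials)) {
    abort(sprintf("Every behavior needs at least %d trials (min %d found).",
                  min_trials, min(per_combo)),
          class = "npc_invalid_input")
  }
  ids <- spike_neuron_ids(spikes)
  n_n <- length(ids)
  labels <- match(trials$combo_id, space$combos$combo_id)
  n_behavior <- nrow(space$combos)
  truth_of <- list(
    presaccade = match(trials$pos_id, space$positions$pos_id),
    direction = match(trials$dir_id, space$directions$dir_id),
    postsaccade = match(trials$post_id, space$postsaccade$post_id)
  )
  marg_of <- list(
    presaccade = marginalization_matrix(space, "presaccade"),
    direction = marginalization_matrix(space, "direction"),
    postsaccade = marginalization_matrix(space, "postsaccade")
  )

  # per-window precomputation: neuron components + bookkeeping
  wins <- list()
  for (spec in objective) {
    for (e in spec$ends) {
      R <- count_matrix(window_counts(spikes, trials, spec$align_event,
                                      c(e - spec$window_ms, e),
                                      neuron_ids = ids))
      comp <- per_neuron_components(R, labels, n_behavior, model,
                                    floor_mu, floor_sigma2)
      wins[[length(wins) + 1]] <- list(
        behavior = spec$behavior, A = comp$A, n_b = comp$n_b,
        LL = apply(comp$A, c(1, 2), sum),
        marg = marg_of[[spec$behavior]], truth = truth_of[[spec$behavior]]
      )
    }
  }
  behaviors <- unique(vapply(wins, function(w) w$behavior, character(1)))

  objective_of <- function(lls) {
    # lls: list of current LL matrices per window
    per_beh <- vapply(behaviors, function(b) {
      k <- which(vapply(wins, function(w) w$behavior, character(1)) == b)
      vals <- vapply(k, function(j) {
        window_accuracy(lls[[j]], wins[[j]]$n_b, labels, wins[[j]]$marg,
                        wins[[j]]$truth, prior_mode)
      }, numeric(1))
      sqrt(mean(vals^2))
    }, numeric(1))
    mean(per_beh)
  }

  lls <- lapply(wins, function(w) w$LL)
  active <- seq_len(n_n)  # positions into ids
  acc_at_size <- tibble::tibble(size = n_n, objective = objective_of(lls))
  removed <- tibble::tibble(step = integer(), neuron_id = integer(),
                            size_after = integer(), objective = numeric())

  step <- 0L
  while (length(active) > 1) {
    scores <- vapply(active, function(i) {
      objective_of(lapply(seq_along(wins),
                          function(j) lls[[j]] - wins[[j]]$A[, , i]))
    }, numeric(1))
    k <- min(batch, length(active) - 1)
    # remove the k candidates whose removal leaves the highest objective;
    # ties resolved toward the lower neuron id
    ord <- order(-scores, ids[active])
    drop_pos <- active[ord[seq_len(k)]]
    for (i in drop_pos) {
      step <- step + 1L
      for (j in seq_along(wins)) lls[[j]] <- lls[[j]] - wins[[j]]$A[, , i]
      active <- setdiff(active, i)
      obj <- objective_of(lls)
      removed <- dplyr::bind_rows(removed, tibble::tibble(
        step = step, neuron_id = ids[i], size_after = length(active),
        objective = obj))
      acc_at_size <- dplyr::bind_rows(acc_at_size, tibble::tibble(
        size = length(active), objective = obj))
    }
  }

  structure(
    list(order = c(removed$neuron_id, ids[active]),
         removed = removed,
         accuracy_at_size = dplyr::arrange(acc_at_size, .data$size),
         objective_spec = objective, model = model),
    class = "rne_ranking"
  )
}

#' @export
print.rne_ranking <- function(x, ...) {
  cat(sprintf("<rne_ranking> %d neurons; full-population objective %.4f; top neuron %d\n",
              length(x$order), x$accuracy_at_size$objective[
                which.max(x$accuracy_at_size$size)],
              x$order[length(x$order)]))
  invisible(x)
}

#' @rdname rne_rank
#' @param x An `rne_ranking`.
#' @param ... Unused.
#' @method tidy rne_ranking
#' @export
tidy.rne_ranking <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$order), neuron_id = x$order,
                 objective_after_removal = c(x$removed$objective, NA_real_))
}

#' Accuracy versus retained population size
#'
#' Reads the objective curve from an RNE ranking: the objective of the best
#' k neurons (the last k in the elimination order) for every visited size.
#'
#' @param ranking An [rne_rank()] result.
#' @return A tibble `size`, `objective`.
#' @export
accuracy_vs_size <- function(ranking) {
  stopifnot(inherits(ranking, "rne_ranking"))
  ranking$accuracy_at_size
}

#' Scale an empirical NPC time course to an optimized reference
#'
#' Empirical populations undersample the behavior space, which biases their
#' NPC downward; the accuracy of an RNE-optimized subset provides a
#' reference. This scales the empirical time course so that its mean
#' accuracy over a reference epoch matches the optimized value, then clips
#' to `[chance, 1]`.
#'
#' @param tc An [npc_timecourse()].
#' @param optimized Scalar reference accuracy (the optimized subset's epoch
#'   mean).
#' @param behavior Behavior variable to scale.
#' @param from,to Reference epoch bounds (times or event names).
#' @param chance Chance floor used for clipping (default 0).
#' @return The time course with `npc` (and `sem`) scaled for `behavior`;
#'   attribute `scale_factor` records the factor applied.
#' @export
bias_correct <- function(tc, optimized, behavior = "direction", from, to,
                         chance = 0) {
  stopifnot(inherits(tc, "npc_timecourse"))
  if (!is.numeric(optimized) || optimized <= 0) {
    abort("`optimized` must be a positive scalar.",
          class = "npc_invalid_argument")
  }
  from <- resolve_epoch_bound(tc, from)
  to <- resolve_epoch_bound(tc, to)
  rows <- tc$behavior == behavior & tc$time >= from & tc$time <= to
  emp <- mean(tc$npc[rows])
  if (!is.finite(emp) || emp <= 0) {
    abort("Empirical epoch mean is zero; scaling undefined.",
          class = "npc_undefined_scaling")
  }
  factor <- optimized / emp
  sel <- tc$behavior == behavior
  tc$npc[sel] <- pmin(1, pmax(chance, tc$npc[sel] * factor))
  tc$sem[sel] <- tc$sem[sel] * factor
  attr(tc, "scale_factor") <- factor
  tc
}
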