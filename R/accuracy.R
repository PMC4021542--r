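# NPC accuracy: per-behavior fraction correct, averaged (unweighted) across
# behaviors, with bootstrap uncertainty.

#' NPC accuracy with bootstrap standard error
#'
#' Computes the prediction accuracy of each behavior (the fraction of trials
#' whose MAP estimate equals the true behavior) and averages them, unweighted,
#' into the accuracy of the neuronal population code (NPC). The standard
#' error is the standard deviation of the NPC over bootstrap resamples of
#' trials (uniform, with replacement, across all trials; set
#' `stratified = TRUE` to resample within behaviors). A behavior with no
#' trials in a given resample is dropped from that resample's average.
#'
#' @param truth True behavior per trial.
#' @param estimate Estimated behavior per trial.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap stream.
#' @param behaviors Optional full behavior set (behaviors never seen in
#'   `truth` are ignored for the average — accuracy is undefined for them).
#' @param stratified Resample within each behavior instead of across all
#'   trials.
#' @return An `npc_result` list: `per_behavior` tibble
#'   (`behavior`, `n_trials`, `accuracy`), `npc`, `sem`, `n_boot`, `boot`
#'   (the bootstrap NPC replicates).
#' @examples
#' r <- npc_accuracy(c(1, 1, 2, 2), c(1, 1, 2, 1), n_boot = 100, seed = 1)
#' r$npc  # mean of accuracies 1.0 and 0.5 = 0.75
#' @export
npc_accuracy <- function(truth, estimate, n_boot = 1000, seed = 1,
                         behaviors = NULL, stratified = FALSE) {
  if (length(truth) == 0 || length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must be non-empty and aligned.",
          class = "npc_invalid_argument")
  }
  behaviors <- behaviors %||% sort(unique(truth))
  behaviors <- behaviors[behaviors %in% truth]
  bi <- match(truth, behaviors)
  correct <- as.numeric(truth == estimate)
  n_bv <- tabulate(bi, nbins = length(behaviors))
  acc <- as.numeric(rowsum(correct, bi)) / n_bv
  npc <- mean(acc)

  n_t <- length(truth)
  boot <- with_seed(derive_seed(seed, 99L), {
    vapply(seq_len(n_boot), function(k) {
      idx <- if (stratified) {
        unlist(lapply(seq_along(behaviors), function(b) {
          w <- which(bi == b)
          w[sample.int(length(w), length(w), replace = TRUE)]
        }))
      } else {
        sample.int(n_t, n_t, replace = TRUE)
      }
      nb <- tabulate(bi[idx], nbins = length(behaviors))
      hits <- tabulate(bi[idx][correct[idx] == 1], nbins = length(behaviors))
      keep <- nb > 0
      mean(hits[keep] / nb[keep])
    }, numeric(1))
  })

  structure(
    list(per_behavior = tibble::tibble(behavior = behaviors,
                                       n_trials = n_bv, accuracy = acc),
         npc = npc, sem = stats::sd(boot), n_boot = n_boot, boot = boot),
    class = "npc_result"
  )
}

#' @export
print.npc_result <- function(x, ...) {
  cat(sprintf("<npc_result> NPC = %.4f +/- %.4f (bootstrap SEM, %d resamples; %d behaviors, %d trials)\n",
              x$npc, x$sem, x$n_boot, nrow(x$per_behavior),
              sum(x$per_behavior$n_trials)))
  invisible(x)
}

#' @rdname npc_accuracy
#' @param x An `npc_result`.
#' @param ... Unused.
#' @method tidy npc_result
#' @export
tidy.npc_result <- function(x, ...) {
  x$per_behavior
}

#' @rdname npc_accuracy
#' @method glance npc_result
#' @export
glance.npc_result <- function(x, ...) {
  tibble::tibble(npc = x$npc, sem = x$sem, n_boot = x$n_boot,
                 n_behaviors = nrow(x$per_behavior),
                 n_trials = sum(x$per_behavior$n_trials))
}

#' Summarize a decoded session across the three behaviors
#'
#' Applies [npc_accuracy()] to the presaccade-position, saccade-direction and
#' postsaccade-position estimates of a [loo_decode()] result.
#'
#' @param decoded An `npc_decode` tibble.
#' @param n_boot,seed,stratified Passed to [npc_accuracy()].
#' @return A tibble with one row per behavior variable: `behavior`, `npc`,
#'   `sem`, `chance` (1/number of behavior values), `n_trials`.
#' @export
npc_summary <- function(decoded, n_boot = 1000, seed = 1, stratified = FALSE) {
  specs <- list(
    presaccade = c("pos_id", "pos_est"),
    direction = c("dir_id", "dir_est"),
    postsaccade = c("post_id", "post_est")
  )
  purrr::imap_dfr(specs, function(cols, nm) {
    r <- npc_accuracy(decoded[[cols[1]]], decoded[[cols[2]]],
                      n_boot = n_boot, seed = seed, stratified = stratified)
    tibble::tibble(behavior = nm, npc = r$npc, sem = r$sem,
                   chance = 1 / length(unique(decoded[[cols[1]]])),
                   n_trials = nrow(decoded))
  })
}
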