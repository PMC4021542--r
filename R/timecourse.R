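# NPC time courses: sliding-window decoding, epoch RMS summaries, and
# onset/peak detection on the smoothed accuracy traces.

#' Time course of NPC accuracy
#'
#' Slides a causal boxcar counting window (length `window_ms`, step
#' `step_ms`) across the task, aligned to `align_event`, and runs the full
#' decoding pipeline (tuning fit, leave-one-out posterior, MAP estimate,
#' per-behavior accuracy, bootstrap SEM) independently at every step, so
#' inference always uses intervals of identical length. The count at time
#' `t` covers `[t - window_ms, t)` — strictly the past.
#'
#' The same bootstrap resamples of trials are reused at every time step, so
#' bootstrap noise does not jitter the shape of the trace and epoch summaries
#' can reuse the replicates.
#'
#' @param spikes Spike tibble from [simulate_spikes()].
#' @param trials Trial table from [simulate_task()].
#' @param space The [behavior_space()].
#' @param align_event `"target_on"` or `"saccade_onset"` (any event column).
#' @param t_range `c(first, last)` window-end times (ms) relative to the
#'   alignment event.
#' @param window_ms,step_ms Window length and step (default 250 / 10 ms).
#' @param model,prior_mode,mode,floor_mu,floor_sigma2 Passed to the decoder
#'   (see [loo_decode()]).
#' @param n_boot Bootstrap resamples per time step (default 200).
#' @param seed Seed for tie-breaking and the bootstrap stream.
#' @return An `npc_timecourse` tibble: `time`, `behavior` (presaccade /
#'   direction / postsaccade), `npc`, `sem`, `clipped`. Attributes carry the
#'   window parameters, the alignment event, mean event times relative to
#'   the alignment (`event_times_rel`), and the bootstrap replicate matrices
#'   (`boot`, one `n_boot` x n-times matrix per behavior).
#' @export
npc_timecourse <- function(spikes, trials, space = behavior_space(),
                           align_event = "target_on",
                           t_range = c(0, 1000), window_ms = 250,
                           step_ms = 10,
                           model = c("poisson", "truncgauss"),
                           prior_mode = c("loo", "full"),
                           mode = c("joint", "marginal"),
                           floor_mu = floor_mu_default,
                           floor_sigma2 = floor_sigma2_default,
                           n_boot = 200, seed = 1) {
  model <- match.arg(model)
  prior_mode <- match.arg(prior_mode)
  mode <- match.arg(mode)
  check_trials(trials)
  cube <- make_bin_cube(spikes, trials, align_event, window_ms, step_ms,
                        t_range)
  t_ends <- seq(t_range[1], t_range[2], by = step_ms)
  n_t <- nrow(trials)

  lab_joint <- match(trials$combo_id, space$combos$combo_id)
  marg <- list(
    presaccade = marginalization_matrix(space, "presaccade"),
    direction = marginalization_matrix(space, "direction"),
    postsaccade = marginalization_matrix(space, "postsaccade")
  )
  truth <- list(
    presaccade = match(trials$pos_id, space$positions$pos_id),
    direction = match(trials$dir_id, space$directions$dir_id),
    postsaccade = match(trials$post_id, space$postsaccade$post_id)
  )
  onehot <- lapply(truth, function(tr) {
    m <- matrix(0, n_t, max(tr))
    m[cbind(seq_len(n_t), tr)] <- 1
    m
  })

  # bootstrap multiplicity matrix, shared across windows
  W <- with_seed(derive_seed(seed, 99L), {
    m <- matrix(0, n_boot, n_t)
    for (k in seq_len(n_boot)) {
      idx <- sample.int(n_t, n_t, replace = TRUE)
      tab <- tabulate(idx, nbins = n_t)
      m[k, ] <- tab
    }
    m
  })
  NB <- lapply(onehot, function(oh) W %*% oh)  # resample behavior counts

  behaviors <- names(marg)
  npc_mat <- matrix(NA_real_, length(t_ends), length(behaviors),
                    dimnames = list(NULL, behaviors))
  sem_mat <- npc_mat
  boot_mats <- lapply(behaviors, function(b) {
    matrix(NA_real_, n_boot, length(t_ends))
  })
  names(boot_mats) <- behaviors
  clipped <- logical(length(t_ends))

  for (w in seq_along(t_ends)) {
    R <- cube_window_counts(cube, t_ends[w])
    clipped[w] <- cube_window_clipped(cube, t_ends[w])
    if (mode == "joint") {
      P <- loo_posterior_matrix(R, lab_joint, nrow(space$combos), model,
                                prior_mode, floor_mu, floor_sigma2)
      P_by <- lapply(marg, function(m) P %*% m)
    } else {
      P_pos <- loo_posterior_matrix(R, truth$presaccade,
                                    nrow(space$positions), model,
                                    prior_mode, floor_mu, floor_sigma2)
      P_dir <- loo_posterior_matrix(R, truth$direction,
                                    nrow(space$directions), model,
                                    prior_mode, floor_mu, floor_sigma2)
      P_joint <- P_pos[, space$combos$pos_id] * P_dir[, space$combos$dir_id]
      P_by <- list(presaccade = P_pos, direction = P_dir,
                   postsaccade = P_joint %*% marg$postsaccade)
    }
    for (b in behaviors) {
      est <- map_rows(P_by[[b]], derive_seed(seed, w, match(b, behaviors)))
      correct <- as.numeric(est == truth[[b]])
      C <- onehot[[b]] * correct
      n_bv <- colSums(onehot[[b]])
      acc <- colSums(C)[n_bv > 0] / n_bv[n_bv > 0]
      npc_mat[w, b] <- mean(acc)
      hits <- W %*% C
      frac <- hits / NB[[b]]
      frac[!is.finite(frac)] <- NA
      boot_npc <- rowMeans(frac, na.rm = TRUE)
      boot_mats[[b]][, w] <- boot_npc
      sem_mat[w, b] <- stats::sd(boot_npc)
    }
  }

  out <- purrr::map_dfr(behaviors, function(b) {
    tibble::tibble(time = t_ends, behavior = b, npc = npc_mat[, b],
                   sem = sem_mat[, b], clipped = clipped)
  })
  ev_rel <- trials[, event_names()] |>
    dplyr::mutate(dplyr::across(dplyr::everything(),
                                ~ .x - trials[[align_event]])) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean))
  attr(out, "align_event") <- align_event
  attr(out, "window_ms") <- window_ms
  attr(out, "step_ms") <- step_ms
  attr(out, "n_boot") <- n_boot
  attr(out, "model") <- model
  attr(out, "event_times_rel") <- ev_rel
  attr(out, "boot") <- boot_mats
  class(out) <- c("npc_timecourse", class(out))
  out
}

resolve_epoch_bound <- function(tc, bound) {
  if (is.character(bound)) {
    ev <- attr(tc, "event_times_rel")
    if (is.null(ev) || !bound %in% names(ev)) {
      abort(sprintf("Unknown epoch bound `%s`.", bound),
            class = "npc_invalid_argument")
    }
    as.numeric(ev[[bound]])
  } else {
    bound
  }
}

#' Root-mean-square NPC accuracy over a task epoch
#'
#' Summarizes a time course between two epoch bounds by the root mean square
#' of the accuracy over the steps in the epoch — the area under the time
#' course normalized by epoch length, so epochs of different durations are
#' comparable. The SEM is computed by applying the same RMS to each
#' bootstrap replicate trace.
#'
#' @param tc An [npc_timecourse()].
#' @param behavior Which behavior variable to summarize.
#' @param from,to Epoch bounds: times in ms relative to the alignment event,
#'   or event names (resolved to session-mean event times).
#' @return A one-row tibble: `behavior`, `from`, `to`, `rms`, `sem`,
#'   `n_steps`.
#' @export
epoch_rms <- function(tc, behavior = "direction", from, to) {
  stopifnot(inherits(tc, "npc_timecourse"))
  from <- resolve_epoch_bound(tc, from)
  to <- resolve_epoch_bound(tc, to)
  rows <- tc$behavior == behavior & tc$time >= from & tc$time <= to
  if (!any(rows)) {
    abort("Epoch contains no time steps.", class = "npc_invalid_argument")
  }
  x <- tc$npc[rows]
  rms <- sqrt(mean(x^2))
  sem <- NA_real_
  boot <- attr(tc, "boot")
  if (!is.null(boot)) {
    idx <- which(tc$time[tc$behavior == behavior] >= from &
                   tc$time[tc$behavior == behavior] <= to)
    bm <- boot[[behavior]][, idx, drop = FALSE]
    sem <- stats::sd(sqrt(rowMeans(bm^2)))
  }
  tibble::tibble(behavior = behavior, from = from, to = to, rms = rms,
                 sem = sem, n_steps = sum(rows))
}

# Truncated-Gaussian smoothing kernel, renormalized where the support is
# clipped at the series edges.
gauss_smooth <- function(x, step_ms, sd_ms = 50, halfwidth_ms = 125) {
  h <- floor(halfwidth_ms / step_ms)
  w <- dnorm(seq(-h, h) * step_ms, 0, sd_ms)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - h):min(n, i + h)
    k <- w[j - i + h + 1]
    out[i] <- sum(x[j] * k) / sum(k)
  }
  out
}

#' Detect the onset and peak of an NPC time course
#'
#' Smooths the accuracy trace with a truncated Gaussian kernel (window
#' `smooth_window_ms`, SD `smooth_sd_ms`), then compares at each step the
#' mean derivative (central differences) over `deriv_span_ms` after versus
#' before that step. The onset maximizes the derivative difference
#' (after - before); the peak maximizes the opposite difference
#' (before - after). A trace whose smoothed range does not exceed
#' `snr_min` times its estimated noise level (noise SD from first
#' differences, propagated through the kernel) is reported as having no
#' detectable structure: marks are `NA` with a `reason`.
#'
#' @param tc An [npc_timecourse()], or any tibble with `time`, `behavior`,
#'   `npc`.
#' @param behavior Behavior variable to analyze.
#' @param smooth_window_ms Total kernel support (default 250 ms).
#' @param smooth_sd_ms Kernel SD (default 50 ms).
#' @param deriv_span_ms Span over which before/after derivatives are averaged
#'   (default 100 ms).
#' @param snr_min Minimum ratio of smoothed range to smoothed noise SD for
#'   marks to be reported (default 7, calibrated so pure-noise traces rarely
#'   yield spurious marks).
#' @return A one-row tibble: `behavior`, `onset_ms`, `peak_ms`, `reason`
#'   (`NA` when marks are defined, otherwise `"flat"` or `"no_structure"`).
#' @export
detect_onset_peak <- function(tc, behavior = "direction",
                              smooth_window_ms = 250, smooth_sd_ms = 50,
                              deriv_span_ms = 100, snr_min = 7) {
  d <- tc[tc$behavior == behavior, , drop = FALSE]
  d <- d[order(d$time), ]
  x <- d$npc
  times <- d$time
  step <- times[2] - times[1]
  n <- length(x)
  empty <- tibble::tibble(behavior = behavior, onset_ms = NA_real_,
                          peak_ms = NA_real_, reason = NA_character_)

  if (diff(range(x)) == 0) {
    empty$reason <- "flat"
    return(empty)
  }
  s <- gauss_smooth(x, step, smooth_sd_ms, smooth_window_ms / 2)

  # noise gate: estimated point-noise SD carried through the kernel
  sigma_raw <- stats::mad(diff(x)) / sqrt(2)
  h <- floor((smooth_window_ms / 2) / step)
  w <- dnorm(seq(-h, h) * step, 0, smooth_sd_ms)
  w <- w / sum(w)
  sigma_smooth <- sigma_raw * sqrt(sum(w^2))
  if (sigma_smooth > 0 && diff(range(s)) < snr_min * sigma_smooth) {
    empty$reason <- "no_structure"
    return(empty)
  }

  deriv <- c(NA, (s[3:n] - s[1:(n - 2)]) / (2 * step), NA)
  span <- max(1L, floor(deriv_span_ms / step))
  lo <- span + 2L
  hi <- n - span - 1L
  if (hi <= lo) {
    empty$reason <- "too_short"
    return(empty)
  }
  stat <- rep(NA_real_, n)
  for (i in lo:hi) {
    after <- mean(deriv[(i + 1):(i + span)])
    before <- mean(deriv[(i - span):(i - 1)])
    stat[i] <- after - before
  }
  onset_i <- which.max(stat)
  peak_i <- which.min(stat)
  tibble::tibble(behavior = behavior, onset_ms = times[onset_i],
                 peak_ms = times[peak_i], reason = NA_character_)
}
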