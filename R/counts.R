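# Spike counting: fixed windows and sliding causal boxcar windows.

# Resolve the neuron id set for a spike table.
spike_neuron_ids <- function(spikes, neuron_ids = NULL) {
  ids <- neuron_ids %||% attr(spikes, "neuron_ids") %||%
    sort(unique(spikes$neuron_id))
  as.integer(ids)
}

#' Count spikes in one window per trial
#'
#' Counts each neuron's spikes in a half-open window `[start, end)` relative
#' to an alignment event, for every trial.
#'
#' @param spikes Spike tibble (`trial_id`, `neuron_id`, `time_ms`), e.g. from
#'   [simulate_spikes()].
#' @param trials Trial table from [simulate_task()].
#' @param align_event Event name to align to (a column of `trials`).
#' @param window `c(start, end)` in ms relative to the event.
#' @param neuron_ids Neuron ids to include; defaults to the ids recorded in
#'   `spikes` (so silent neurons still get zero columns).
#' @return A count table: `trial_id`, behavior labels, one column `n<id>` per
#'   neuron.
#' @export
window_counts <- function(spikes, trials, align_event = "go_cue",
                          window = c(-250, 0), neuron_ids = NULL) {
  check_trials(trials)
  ids <- spike_neuron_ids(spikes, neuron_ids)
  align <- trials[[align_event]][match(spikes$trial_id, trials$trial_id)]
  rel <- spikes$time_ms - align
  keep <- rel >= window[1] & rel < window[2]
  t_idx <- match(spikes$trial_id[keep], trials$trial_id)
  n_idx <- match(spikes$neuron_id[keep], ids)
  ok <- !is.na(n_idx)
  counts <- matrix(0L, nrow(trials), length(ids))
  if (any(ok)) {
    tab <- tabulate((n_idx[ok] - 1L) * nrow(trials) + t_idx[ok],
                    nbins = nrow(trials) * length(ids))
    counts <- matrix(tab, nrow(trials), length(ids))
  }
  colnames(counts) <- paste0("n", ids)
  dplyr::bind_cols(
    trials[, c("trial_id", "combo_id", "pos_id", "dir_id", "post_id")],
    tibble::as_tibble(counts)
  )
}

# Pre-binned spike cube for sliding-window extraction. Bins aligned spike
# times into `step_ms` bins covering [t_range[1] - window_ms, t_range[2]),
# and stores the cumulative count per (trial, neuron) row so that the count
# in any causal window [t - window_ms, t) on the step grid is a difference
# of two columns.
make_bin_cube <- function(spikes, trials, align_event, window_ms, step_ms,
                          t_range, neuron_ids = NULL) {
  if (window_ms %% step_ms != 0) {
    abort("`window_ms` must be a multiple of `step_ms`.",
          class = "npc_invalid_argument")
  }
  ids <- spike_neuron_ids(spikes, neuron_ids)
  n_t <- nrow(trials)
  n_n <- length(ids)
  e0 <- t_range[1] - window_ms
  nbins <- as.integer(round((t_range[2] - e0) / step_ms))

  align <- trials[[align_event]][match(spikes$trial_id, trials$trial_id)]
  rel <- spikes$time_ms - align
  bin <- floor((rel - e0) / step_ms) + 1
  keep <- bin >= 1 & bin <= nbins
  t_idx <- match(spikes$trial_id[keep], trials$trial_id)
  n_idx <- match(spikes$neuron_id[keep], ids)
  ok <- !is.na(n_idx)
  row <- (t_idx[ok] - 1L) * n_n + n_idx[ok]
  tab <- tabulate((bin[keep][ok] - 1L) * (n_t * n_n) + row,
                  nbins = nbins * n_t * n_n)
  m <- matrix(tab, n_t * n_n, nbins)
  for (j in seq_len(nbins - 1) + 1L) m[, j] <- m[, j] + m[, j - 1L]
  cs <- cbind(0L, m)

  align_all <- trials[[align_event]]
  list(cs = cs, e0 = e0, step = step_ms, window = window_ms, nbins = nbins,
       n_trial = n_t, n_neuron = n_n, ids = ids,
       align_times = align_all, trial_end = trials$trial_end)
}

# Count matrix (trials x neurons) for the causal window [t_end - window, t_end).
cube_window_counts <- function(cube, t_end) {
  j1 <- as.integer(round((t_end - cube$e0) / cube$step))
  j0 <- j1 - as.integer(cube$window / cube$step)
  if (j0 < 0 || j1 > cube$nbins) {
    abort("Window outside the binned range.", class = "npc_invalid_argument")
  }
  v <- cube$cs[, j1 + 1L] - cube$cs[, j0 + 1L]
  m <- matrix(v, cube$n_trial, cube$n_neuron, byrow = TRUE)
  colnames(m) <- paste0("n", cube$ids)
  m
}

# TRUE if the window [t_end - window, t_end) falls partly outside some
# trial's recorded span [0, trial_end] on the trial clock.
cube_window_clipped <- function(cube, t_end) {
  a <- cube$align_times + t_end - cube$window
  b <- cube$align_times + t_end
  any(a < 0 | b > cube$trial_end)
}

#' Sliding causal spike counts
#'
#' Computes spike counts in causal boxcar windows of length `window_ms`
#' sliding in `step_ms` steps: the count timestamped at `t` covers
#' `[t - window_ms, t)`, looking only into the past. Windows that extend
#' beyond a trial's recorded span are flagged as clipped (column `clipped`),
#' never padded.
#'
#' @inheritParams window_counts
#' @param window_ms Window length in ms (default 250).
#' @param step_ms Step between window end points in ms (default 10).
#' @param t_range `c(first, last)` window end times in ms relative to the
#'   alignment event.
#' @return A tibble with `time` (window end, ms relative to the event),
#'   `clipped`, `trial_id`, and one count column per neuron.
#' @export
sliding_counts <- function(spikes, trials, align_event = "target_on",
                           window_ms = 250, step_ms = 10,
                           t_range = c(0, 1000), neuron_ids = NULL) {
  check_trials(trials)
  cube <- make_bin_cube(spikes, trials, align_event, window_ms, step_ms,
                        t_range, neuron_ids)
  t_ends <- seq(t_range[1], t_range[2], by = step_ms)
  purrr::map_dfr(t_ends, function(t_end) {
    m <- cube_window_counts(cube, t_end)
    dplyr::bind_cols(
      tibble::tibble(time = t_end,
                     clipped = cube_window_clipped(cube, t_end),
                     trial_id = trials$trial_id),
      tibble::as_tibble(m)
    )
  })
}

# Extract the neuron count matrix from a count table.
count_matrix <- function(counts) {
  cols <- grep("^n[0-9]+$", names(counts), value = TRUE)
  m <- as.matrix(counts[, cols])
  storage.mode(m) <- "double"
  m
}
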