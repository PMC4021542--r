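#' Timing configuration for the delayed memory saccade task
#'
#' Epoch durations in milliseconds. Defaults follow the standard protocol:
#' 1000 ms fixation, a 300 ms target flash, a memory delay of 1300 +/- 200 ms
#' drawn uniformly, 500 ms of postsaccade fixation in darkness (fixation I)
#' and 500 ms of fixation on the reilluminated target (fixation II).
#' Fixation-acquisition latency and saccade reaction time are drawn from a
#' truncated normal (the protocol fixes no distribution; ground-truth event
#' times are stored with every trial, so no detection step depends on it).
#'
#' @param fixation_ms Fixation duration before target onset.
#' @param target_ms Target flash duration.
#' @param memory_ms Mean memory-delay duration.
#' @param memory_jitter_ms Half-width of the uniform memory-delay jitter.
#' @param fixation1_ms Duration of postsaccade fixation I.
#' @param fixation2_ms Duration of fixation II (until reward / trial end).
#' @param rt_mean_ms,rt_sd_ms,rt_min_ms Saccade reaction-time distribution
#'   (truncated normal), also used for fixation acquisition latency.
#' @param saccade_ms Nominal saccade flight time from onset to landing.
#' @return A named list of class `task_timing`.
#' @export
task_timing <- function(fixation_ms = 1000, target_ms = 300,
                        memory_ms = 1300, memory_jitter_ms = 200,
                        fixation1_ms = 500, fixation2_ms = 500,
                        rt_mean_ms = 200, rt_sd_ms = 30, rt_min_ms = 80,
                        saccade_ms = 40) {
  cfg <- list(fixation_ms = fixation_ms, target_ms = target_ms,
              memory_ms = memory_ms, memory_jitter_ms = memory_jitter_ms,
              fixation1_ms = fixation1_ms, fixation2_ms = fixation2_ms,
              rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
              rt_min_ms = rt_min_ms, saccade_ms = saccade_ms)
  if (any(vapply(cfg, function(v) !is.numeric(v) || length(v) != 1 || v < 0,
                 logical(1)))) {
    abort("All timing parameters must be single non-negative numbers.",
          class = "npc_invalid_argument")
  }
  structure(cfg, class = "task_timing")
}

# Event names in their within-trial order; the trial clock starts at
# fixation light onset (fixation_on = 0).
event_names <- function() {
  c("fixation_on", "fixation_acquired", "target_on", "target_off",
    "go_cue", "saccade_onset", "fixation1_acquired", "fixation2_acquired",
    "trial_end")
}

#' Simulate a randomized session of the grid saccade task
#'
#' Generates `n_blocks` blocks of trials. Within each block every
#' (presaccade position, direction) combination occurs exactly once, in an
#' independent random order per block, so every combination is sampled
#' `n_blocks` times overall (11 blocks on the 3 x 3 grid give the standard
#' 11 x 72 = 792 trials). Only correct trials are generated. Event times are
#' laid out on a per-trial clock starting at fixation light onset, with the
#' memory delay jittered uniformly and the reaction time drawn from the
#' configured truncated normal.
#'
#' @param space A [behavior_space()].
#' @param n_blocks Number of blocks (default 11).
#' @param timing A [task_timing()] configuration.
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   schedule exactly.
#' @return A tibble with one row per trial: `trial_id`, `block`, behavior
#'   labels (`combo_id`, `pos_id`, `dir_id`, `post_id`, and the grid
#'   coordinates `pre_x`, `pre_y`, `post_x`, `post_y`), and one column per
#'   task event time in ms (see [task_timing()] for the schedule).
#' @examples
#' sp <- behavior_space()
#' trials <- simulate_task(sp, n_blocks = 1, seed = 1)
#' nrow(trials)  # 72
#' @export
simulate_task <- function(space, n_blocks = 11, timing = task_timing(),
                          seed = 1) {
  stopifnot(inherits(space, "behavior_space"))
  n_blocks <- check_scalar_count(n_blocks, "n_blocks", min = 1)
  if (!inherits(timing, "task_timing")) {
    abort("`timing` must be a `task_timing()` object.",
          class = "npc_invalid_argument")
  }
  n_combo <- nrow(space$combos)

  with_seed(seed, {
    order_in_block <- lapply(seq_len(n_blocks), function(b) sample.int(n_combo))
    combo_seq <- unlist(lapply(seq_len(n_blocks),
                               function(b) order_in_block[[b]]))
    n <- length(combo_seq)

    acquire <- rtruncnorm(n, timing$rt_mean_ms, timing$rt_sd_ms,
                          timing$rt_min_ms)
    memory <- runif(n, timing$memory_ms - timing$memory_jitter_ms,
                    timing$memory_ms + timing$memory_jitter_ms)
    rt <- rtruncnorm(n, timing$rt_mean_ms, timing$rt_sd_ms, timing$rt_min_ms)

    fixation_on <- rep(0, n)
    fixation_acquired <- fixation_on + acquire
    target_on <- fixation_acquired + timing$fixation_ms
    target_off <- target_on + timing$target_ms
    go_cue <- target_off + memory
    saccade_onset <- go_cue + rt
    fixation1_acquired <- saccade_onset + timing$saccade_ms
    fixation2_acquired <- fixation1_acquired + timing$fixation1_ms
    trial_end <- fixation2_acquired + timing$fixation2_ms

    trials <- tibble::tibble(
      trial_id = seq_len(n),
      block = rep(seq_len(n_blocks), each = n_combo),
      combo_id = combo_seq
    ) |>
      dplyr::left_join(space$combos, by = "combo_id") |>
      dplyr::left_join(
        dplyr::rename(space$positions, pre_x = "x", pre_y = "y"),
        by = "pos_id"
      ) |>
      dplyr::left_join(
        dplyr::rename(space$postsaccade, post_x = "x", post_y = "y"),
        by = "post_id"
      ) |>
      dplyr::mutate(
        fixation_on = fixation_on,
        fixation_acquired = round(fixation_acquired, 3),
        target_on = round(target_on, 3),
        target_off = round(target_off, 3),
        go_cue = round(go_cue, 3),
        saccade_onset = round(saccade_onset, 3),
        fixation1_acquired = round(fixation1_acquired, 3),
        fixation2_acquired = round(fixation2_acquired, 3),
        trial_end = round(trial_end, 3)
      )
    attr(trials, "space") <- space
    trials
  })
}

# Validate that a trial table carries the columns downstream stages need.
check_trials <- function(trials) {
  need <- c("trial_id", "combo_id", "pos_id", "dir_id", "post_id",
            event_names())
  missing <- setdiff(need, names(trials))
  if (length(missing) > 0) {
    abort(paste0("Trial table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "npc_invalid_input")
  }
  ev <- as.matrix(trials[, event_names()])
  if (any(apply(ev, 1, function(r) any(diff(r) < 0)))) {
    abort("Event times must be non-decreasing in task order within each trial.",
          class = "npc_invalid_input")
  }
  invisible(trials)
}
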