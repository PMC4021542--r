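# End-to-end pipeline: simulate a session, decode it, and write every
# artifact with a reproducible configuration header.

#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run. All randomness derives from
#' `seed`; identical configurations give byte-identical outputs.
#'
#' @param seed Master seed.
#' @param n_neurons Population size.
#' @param archetype Population archetype (see [make_population()]).
#' @param n_blocks Task blocks.
#' @param model Likelihood model.
#' @param prior_mode,mode Decoder options (see [loo_decode()]).
#' @param decode_align,decode_window Counting window for the single-window
#'   decode stage.
#' @param n_boot Bootstrap resamples.
#' @param timecourse Compute the NPC time course? (logical)
#' @param tc_align,tc_range Time-course alignment and range.
#' @param rne Run Recursive Neuronal Elimination? (logical)
#' @param ... Extra arguments stored verbatim (e.g. population hyperparameter
#'   overrides passed through to [make_population()]).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_neurons = 20, archetype = "tuned",
                       n_blocks = 11, model = "poisson",
                       prior_mode = "loo", mode = "joint",
                       decode_align = "go_cue", decode_window = c(-250, 0),
                       n_boot = 200, timecourse = FALSE,
                       tc_align = "target_on", tc_range = c(0, 1000),
                       rne = FALSE, ...) {
  structure(c(list(seed = seed, n_neurons = n_neurons, archetype = archetype,
                   n_blocks = n_blocks, model = model,
                   prior_mode = prior_mode, mode = mode,
                   decode_align = decode_align,
                   decode_window = decode_window, n_boot = n_boot,
                   timecourse = timecourse, tc_align = tc_align,
                   tc_range = tc_range, rne = rne), list(...)),
            class = "run_config")
}

#' Run the full pipeline into a directory
#'
#' Executes simulate-task, simulate-spikes, decode (single window),
#' optionally the NPC time course and RNE, writing each artifact as
#' delimited text with a metadata header that records the configuration
#' hash and seed. Stage timings are logged with `message()`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- sprintf("%08x", sum(utf8ToInt(paste(
    names(config), vapply(config, function(v) paste(format(v), collapse = ","),
                          ""), collapse = ";"))))
  meta <- list(config = cfg_hash, seed = config$seed)
  paths <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)), class = "npc_stage_error")
    })
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  space <- behavior_space()
  trials <- stage("simulate-task",
                  simulate_task(space, config$n_blocks, seed = config$seed))
  paths$trials <- file.path(out_dir, "trials.csv")
  write_trials(trials, paths$trials)

  pop_args <- config[intersect(names(config),
                               setdiff(names(formals(make_population)),
                                       c("n", "archetype", "seed")))]
  pop <- stage("make-population", do.call(make_population, c(
    list(n = config$n_neurons, archetype = config$archetype,
         seed = derive_seed(config$seed, 11L)), pop_args)))
  paths$population <- file.path(out_dir, "population.yaml")
  write_population(pop, paths$population)

  spikes <- stage("simulate-spikes",
                  simulate_spikes(pop, trials,
                                  seed = derive_seed(config$seed, 12L)))
  paths$spikes <- file.path(out_dir, "spikes.csv")
  write_spikes(spikes, paths$spikes)

  counts <- window_counts(spikes, trials, config$decode_align,
                          config$decode_window)
  decoded <- stage("decode",
                   loo_decode(counts, space, config$model,
                              config$prior_mode, config$mode,
                              seed = derive_seed(config$seed, 13L)))
  paths$decode <- file.path(out_dir, "decode.csv")
  write_table(decoded, paths$decode, meta)
  summ <- npc_summary(decoded, n_boot = config$n_boot,
                      seed = derive_seed(config$seed, 14L))
  paths$summary <- file.path(out_dir, "npc_summary.csv")
  write_table(summ, paths$summary, meta)

  if (isTRUE(config$timecourse)) {
    tc <- stage("timecourse",
                npc_timecourse(spikes, trials, space, config$tc_align,
                               config$tc_range, model = config$model,
                               prior_mode = config$prior_mode,
                               mode = config$mode, n_boot = config$n_boot,
                               seed = derive_seed(config$seed, 15L)))
    paths$timecourse <- file.path(out_dir, "timecourse.csv")
    write_table(tc, paths$timecourse, meta)
  }
  if (isTRUE(config$rne)) {
    rk <- stage("rne", rne_rank(spikes, trials, space, config$model,
                                config$prior_mode,
                                min_trials = min(9, config$n_blocks)))
    paths$rne <- file.path(out_dir, "rne.csv")
    write_table(tidy(rk), paths$rne, meta)
  }
  invisible(paths)
}
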