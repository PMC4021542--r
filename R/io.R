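# Plain-text readers and writers. Every file is delimited text with a
# small `# key: value` metadata header so runs diff cleanly and can be
# reproduced from the file alone.

write_meta <- function(path, meta) {
  lines <- c("# npcdecode",
             vapply(names(meta), function(k) {
               sprintf("# %s: %s", k, format(meta[[k]]))
             }, character(1)))
  writeLines(lines, path)
}

read_meta <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[startsWith(lines, "# ")]
  lines <- lines[grepl(":", lines)]
  kv <- strsplit(sub("^# ", "", lines), ": ", fixed = TRUE)
  kv <- kv[lengths(kv) == 2]
  stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, 1, FUN.VALUE = ""))
}

#' Write / read a trial table
#'
#' One row per trial with behavior labels and event times in ms (3 decimal
#' places). The grid geometry (`extent`, `spacing`) travels in the metadata
#' header so the behavior space is reconstructed on read.
#'
#' @param trials A [simulate_task()] tibble.
#' @param path File path.
#' @export
write_trials <- function(trials, path) {
  space <- attr(trials, "space")
  write_meta(path, list(kind = "trials", extent = space$extent,
                        spacing = space$spacing))
  readr::write_csv(trials, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  meta <- read_meta(path)
  trials <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  attr(trials, "space") <- behavior_space(as.integer(meta$extent),
                                          as.numeric(meta$spacing))
  check_trials(trials)
  trials
}

#' Write / read a spike table
#'
#' One row per spike: `trial_id`, `neuron_id`, `time_ms`. The full neuron id
#' set is recorded in the header so silent neurons survive the round trip.
#'
#' @param spikes A [simulate_spikes()] tibble.
#' @param path File path.
#' @export
write_spikes <- function(spikes, path) {
  ids <- spike_neuron_ids(spikes)
  write_meta(path, list(kind = "spikes",
                        neuron_ids = paste(ids, collapse = " ")))
  readr::write_csv(spikes, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  meta <- read_meta(path)
  spikes <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!is.null(meta$neuron_ids)) {
    attr(spikes, "neuron_ids") <-
      as.integer(strsplit(meta$neuron_ids, " ")[[1]])
  }
  spikes
}

#' Write / read a neuron population
#'
#' Serializes all tuning hyperparameters as YAML.
#'
#' @param pop A [make_population()] tibble.
#' @param path File path.
#' @export
write_population <- function(pop, path) {
  yaml::write_yaml(list(kind = "population",
                        neurons = lapply(seq_len(nrow(pop)), function(i) {
                          as.list(pop[i, ])
                        })), path, precision = 15)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  obj <- yaml::read_yaml(path)
  pop <- dplyr::bind_rows(lapply(obj$neurons, tibble::as_tibble))
  make_population(nrow(pop), archetype = "custom", neurons = pop)
}

#' Write a count table or decode result
#'
#' @param x A tibble (count table, `npc_decode` result, time course, ...).
#' @param path File path.
#' @param meta Optional named list added to the metadata header.
#' @export
write_table <- function(x, path, meta = list()) {
  write_meta(path, c(list(kind = class(x)[1]), meta))
  readr::write_csv(tibble::as_tibble(x), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
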