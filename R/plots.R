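# ggplot2 methods for the result objects.

#' Plot an NPC time course
#'
#' Accuracy trace with its bootstrap-SEM ribbon, one facet per behavior,
#' with the chance level of each behavior as a dotted line.
#'
#' @param object An [npc_timecourse()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot npc_timecourse
#' @export
autoplot.npc_timecourse <- function(object, ...) {
  chance <- tibble::tibble(
    behavior = c("presaccade", "direction", "postsaccade"),
    chance = c(1 / 9, 1 / 8, 1 / 25)
  )
  d <- dplyr::left_join(tibble::as_tibble(object), chance, by = "behavior")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$npc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$npc - .data$sem,
                                      ymax = .data$npc + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$chance),
                        linetype = "dotted") +
    ggplot2::facet_wrap(~behavior, ncol = 1) +
    ggplot2::labs(
      x = sprintf("time relative to %s (ms)", attr(object, "align_event")),
      y = "NPC accuracy"
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot accuracy versus retained population size
#'
#' @param object An [rne_rank()] ranking.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rne_ranking
#' @export
autoplot.rne_ranking <- function(object, ...) {
  ggplot2::ggplot(accuracy_vs_size(object),
                  ggplot2::aes(x = .data$size, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "retained population size (best-k neurons)",
                  y = "objective accuracy") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot a posterior distribution over behaviors
#'
#' @param object An `npc_posterior` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot npc_posterior
#' @export
autoplot.npc_posterior <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$behavior), y = .data$prob)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "behavior", y = "posterior probability") +
    ggplot2::theme_minimal()
}
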