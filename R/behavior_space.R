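#' Enumerate the oculomotor behavior space of the grid saccade task
#'
#' Builds the discrete behavior space of a delayed memory saccade task on a
#' Cartesian grid: the fixation (presaccade) positions on an
#' `extent` x `extent` grid, the 8 saccade directions to neighboring nodes
#' (45-degree increments), every (position, direction) combination, and the
#' postsaccade positions obtained as the vector sum of a presaccade position
#' and a saccade displacement. For the standard 3 x 3 grid with 8-degree
#' spacing this yields 9 presaccade positions, 8 directions, 72 combinations
#' and a 5 x 5 = 25-node postsaccade grid.
#'
#' Cardinal saccades travel `spacing` degrees; diagonal saccades travel
#' `spacing * sqrt(2)` degrees. The direction label is the 8-way index only:
#' amplitude is implied by the grid, not decoded.
#'
#' @param extent Number of grid nodes per side of the presaccade grid
#'   (default 3).
#' @param spacing Grid spacing in degrees of visual angle (default 8).
#' @return A `behavior_space` object: a list with tibbles `positions`
#'   (`pos_id`, `x`, `y`), `directions` (`dir_id`, `angle_deg`, `dx`, `dy`),
#'   `postsaccade` (`post_id`, `x`, `y`) and `combos`
#'   (`combo_id`, `pos_id`, `dir_id`, `post_id`), plus `extent` and `spacing`.
#' @examples
#' sp <- behavior_space()
#' nrow(sp$combos)  # 72
#' @export
behavior_space <- function(extent = 3, spacing = 8) {
  extent <- check_scalar_count(extent, "extent", min = 1)
  if (!is.numeric(spacing) || length(spacing) != 1 || is.na(spacing) ||
      spacing <= 0) {
    abort("`spacing` must be a single positive number.",
          class = "npc_invalid_argument")
  }

  offs <- spacing * (seq_len(extent) - (extent + 1) / 2)
  positions <- tidyr::expand_grid(y = offs, x = offs) |>
    dplyr::arrange(.data$y, .data$x) |>
    dplyr::mutate(pos_id = dplyr::row_number(), .before = 1)

  # unit steps to the 8 neighboring nodes, counterclockwise from +x
  step_x <- c(1, 1, 0, -1, -1, -1, 0, 1)
  step_y <- c(0, 1, 1, 1, 0, -1, -1, -1)
  directions <- tibble::tibble(
    dir_id = 1:8,
    angle_deg = 45 * (0:7),
    dx = spacing * step_x,
    dy = spacing * step_y
  )

  combos <- tidyr::expand_grid(pos_id = positions$pos_id,
                               dir_id = directions$dir_id) |>
    dplyr::arrange(.data$pos_id, .data$dir_id) |>
    dplyr::mutate(combo_id = dplyr::row_number(), .before = 1) |>
    dplyr::left_join(positions, by = "pos_id") |>
    dplyr::left_join(directions, by = "dir_id") |>
    dplyr::mutate(post_x = .data$x + .data$dx, post_y = .data$y + .data$dy)

  postsaccade <- combos |>
    dplyr::distinct(x = .data$post_x, y = .data$post_y) |>
    dplyr::arrange(.data$y, .data$x) |>
    dplyr::mutate(post_id = dplyr::row_number(), .before = 1)

  combos <- combos |>
    dplyr::left_join(
      dplyr::rename(postsaccade, post_x = "x", post_y = "y"),
      by = c("post_x", "post_y")
    ) |>
    dplyr::select("combo_id", "pos_id", "dir_id", "post_id")

  structure(
    list(positions = positions, directions = directions,
         postsaccade = postsaccade, combos = combos,
         extent = extent, spacing = spacing),
    class = "behavior_space"
  )
}

#' @export
print.behavior_space <- function(x, ...) {
  cat(sprintf(
    "<behavior_space> %dx%d grid, %g deg spacing: %d positions, %d directions, %d combos, %d postsaccade positions\n",
    x$extent, x$extent, x$spacing, nrow(x$positions), nrow(x$directions),
    nrow(x$combos), nrow(x$postsaccade)
  ))
  invisible(x)
}

#' Compose a presaccade position and saccade direction into the postsaccade position
#'
#' The postsaccade eye position is the exact vector sum of the presaccade
#' position and the saccade displacement on the grid. Vectorized over
#' `pos_id` / `dir_id`.
#'
#' @param space A [behavior_space()].
#' @param pos_id Presaccade position id(s).
#' @param dir_id Direction id(s), 1..8.
#' @return A tibble with columns `pos_id`, `dir_id`, `post_id`, `x`, `y`
#'   (postsaccade coordinates in degrees).
#' @export
compose_postsaccade <- function(space, pos_id, dir_id) {
  stopifnot(inherits(space, "behavior_space"))
  if (any(!pos_id %in% space$positions$pos_id) ||
      any(!dir_id %in% space$directions$dir_id)) {
    abort("`pos_id`/`dir_id` must index into the behavior space.",
          class = "npc_invalid_argument")
  }
  tibble::tibble(pos_id = pos_id, dir_id = dir_id) |>
    dplyr::left_join(space$combos, by = c("pos_id", "dir_id")) |>
    dplyr::left_join(space$postsaccade, by = "post_id") |>
    dplyr::select("pos_id", "dir_id", "post_id", "x", "y")
}

# Indicator matrices mapping the joint combo space onto each marginal
# behavior set; columns sum a posterior over combos into a marginal posterior.
marginalization_matrix <- function(space, behavior = c("presaccade", "direction",
                                                       "postsaccade")) {
  behavior <- match.arg(behavior)
  n_combo <- nrow(space$combos)
  target <- switch(behavior,
    presaccade = space$combos$pos_id,
    direction = space$combos$dir_id,
    postsaccade = space$combos$post_id
  )
  n_target <- switch(behavior,
    presaccade = nrow(space$positions),
    direction = nrow(space$directions),
    postsaccade = nrow(space$postsaccade)
  )
  m <- matrix(0, n_combo, n_target)
  m[cbind(seq_len(n_combo), target)] <- 1
  m
}
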