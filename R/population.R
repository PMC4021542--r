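#' Build a population of model neurons
#'
#' Constructs a population of independent model neurons whose firing rate for
#' a trial is baseline rate, modulated multiplicatively by (i) a circular
#' bell-shaped (von Mises) saccade-direction tuning curve active once the
#' target has been shown, (ii) a planar eye-position gain field (linear in x
#' and y, floored at zero), and (iii) an epoch-dependent gain profile
#' (fixation, visual transient, sustained memory, perisaccadic burst, and two
#' postsaccadic components). Spike counts are Poisson given the rate, matching
#' the decoder's likelihood model.
#'
#' Archetypes:
#' * `"tuned"` — preferred directions tile `[0, 360)` with seeded jitter;
#'   modulation depths and gain-field slopes drawn from the given ranges.
#' * `"untuned"` — zero modulation depth and flat gain fields: rates are
#'   constant across behaviors, so decoding must sit at chance.
#' * `"duplicate-pair"` — as `"tuned"`, but neuron 2 is an exact copy of
#'   neuron 1 (useful for studying redundancy in neuron ranking).
#' * `"custom"` — supply a complete `neurons` tibble.
#'
#' @param n Number of neurons.
#' @param archetype One of `"tuned"`, `"untuned"`, `"duplicate-pair"`,
#'   `"custom"`.
#' @param baseline_range Range (spikes/s) from which baseline rates are drawn.
#' @param depth_range Range (spikes/s) for the direction modulation depth.
#' @param kappa von Mises concentration of the direction tuning (unitless).
#' @param gain_range Range (gain per degree) for the planar gain-field slopes
#'   in x and y; the gain-field offset is 1, and the total positional gain is
#'   floored at 0.
#' @param epoch_gains Named numeric vector of multiplicative epoch gains with
#'   names `fixation`, `visual`, `memory`, `perisaccadic`, `postsaccadic1`,
#'   `postsaccadic2`.
#' @param peri_lead_ms Time before saccade onset at which the perisaccadic
#'   gain switches on.
#' @param peri_tail_ms Time after saccade onset at which it switches off.
#' @param neurons For `archetype = "custom"`: a tibble with the columns of a
#'   population (see Value).
#' @param seed Integer seed for the neuron parameter draws.
#' @return A tibble of class `neuron_population`, one row per neuron:
#'   `neuron_id`, `baseline`, `pref_deg`, `kappa`, `depth`, `gain_x`,
#'   `gain_y`, the six epoch gains (`g_fixation` ... `g_postsaccadic2`),
#'   `peri_lead_ms`, `peri_tail_ms`.
#' @examples
#' pop <- make_population(8, "untuned", seed = 1)
#' @export
make_population <- function(n, archetype = c("tuned", "untuned",
                                             "duplicate-pair", "custom"),
                            baseline_range = c(5, 15),
                            depth_range = c(8, 24),
                            kappa = 2,
                            gain_range = c(-0.02, 0.02),
                            epoch_gains = c(fixation = 1, visual = 2.5,
                                            memory = 1.6, perisaccadic = 2,
                                            postsaccadic1 = 1.5,
                                            postsaccadic2 = 1.1),
                            peri_lead_ms = 80, peri_tail_ms = 100,
                            neurons = NULL, seed = 1) {
  archetype <- tryCatch(match.arg(archetype),
                        error = function(e) abort(
                          "Unknown archetype.", class = "npc_invalid_argument"))
  n <- check_scalar_count(n, "n", min = 1)
  eg_names <- c("fixation", "visual", "memory", "perisaccadic",
                "postsaccadic1", "postsaccadic2")
  if (!all(eg_names %in% names(epoch_gains))) {
    abort("`epoch_gains` must name all six epochs.",
          class = "npc_invalid_argument")
  }

  if (archetype == "custom") {
    if (is.null(neurons)) {
      abort("`archetype = \"custom\"` requires a `neurons` tibble.",
            class = "npc_invalid_argument")
    }
    pop <- tibble::as_tibble(neurons)
  } else {
    pop <- with_seed(seed, {
      pref <- (seq(0, 360, length.out = n + 1)[seq_len(n)] +
                 runif(n, -180 / n, 180 / n)) %% 360
      tuned <- archetype %in% c("tuned", "duplicate-pair")
      tibble::tibble(
        neuron_id = seq_len(n),
        baseline = runif(n, baseline_range[1], baseline_range[2]),
        pref_deg = pref,
        kappa = kappa,
        depth = if (tuned) runif(n, depth_range[1], depth_range[2]) else 0,
        gain_x = if (tuned) runif(n, gain_range[1], gain_range[2]) else 0,
        gain_y = if (tuned) runif(n, gain_range[1], gain_range[2]) else 0,
        g_fixation = epoch_gains[["fixation"]],
        g_visual = epoch_gains[["visual"]],
        g_memory = epoch_gains[["memory"]],
        g_perisaccadic = epoch_gains[["perisaccadic"]],
        g_postsaccadic1 = epoch_gains[["postsaccadic1"]],
        g_postsaccadic2 = epoch_gains[["postsaccadic2"]],
        peri_lead_ms = peri_lead_ms,
        peri_tail_ms = peri_tail_ms
      )
    })
    if (archetype == "duplicate-pair") {
      if (n < 2) {
        abort("`duplicate-pair` needs n >= 2.", class = "npc_invalid_argument")
      }
      pop[2, setdiff(names(pop), "neuron_id")] <-
        pop[1, setdiff(names(pop), "neuron_id")]
    }
  }

  need <- c("neuron_id", "baseline", "pref_deg", "kappa", "depth",
            "gain_x", "gain_y", paste0("g_", eg_names),
            "peri_lead_ms", "peri_tail_ms")
  missing <- setdiff(need, names(pop))
  if (length(missing) > 0) {
    abort(paste0("Population is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "npc_invalid_argument")
  }
  class(pop) <- c("neuron_population", class(tibble::tibble()))
  pop
}

# von Mises bump with unit peak at the preferred direction.
vm_bump <- function(angle_deg, pref_deg, kappa) {
  exp(kappa * (cos((angle_deg - pref_deg) * pi / 180) - 1))
}

# Planar eye-position gain, floored at zero.
position_gain <- function(pop, x, y) {
  pmax(0, 1 + pop$gain_x * x + pop$gain_y * y)
}

# Mean rate (spikes/s) of every neuron in `pop` for one trial's behavior in
# one epoch. `target_shown` gates the direction term: before the target
# appears the planned direction cannot drive the neuron. `eye` selects which
# eye position feeds the gain field.
neuron_rates <- function(pop, space, dir_id, pos_xy, epoch_gain_col,
                         target_shown) {
  angle <- space$directions$angle_deg[dir_id]
  dir_term <- if (target_shown) {
    pop$depth * vm_bump(angle, pop$pref_deg, pop$kappa)
  } else {
    0
  }
  (pop$baseline + dir_term) * pop[[epoch_gain_col]] *
    position_gain(pop, pos_xy[1], pos_xy[2])
}
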