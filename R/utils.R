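# Internal helpers shared across modules.

# Evaluate `expr` with the global RNG seeded from `seed`, restoring the
# caller's RNG state afterwards so package functions never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation: mixes a master seed with one or two
# stream indices into a 31-bit integer. Used to give each (neuron, trial)
# pair its own spike-generation stream and to separate tie-break/bootstrap
# streams from the main stream.
derive_seed <- function(master, a, b = 0L) {
  m <- 2147483647
  x <- (as.double(master) %% m + 1)
  x <- (x * 2654435761 + as.double(a) * 40503 + as.double(b) * 69069) %% m
  # a second mixing round decorrelates consecutive stream indices
  x <- (x * 48271 + 12345) %% m
  as.integer(x)
}

# Truncated-normal draw by rejection; used for reaction times and fixation
# acquisition latencies (lower truncation keeps latencies physiological).
rtruncnorm <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower)
  }
  out
}

check_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "npc_invalid_argument")
  }
  as.integer(x)
}
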