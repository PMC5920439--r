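# Internal helpers shared across the package.

# Round half away from zero (base round() is round-half-even).  All reported
# percentages use 2 decimals, matching how clinical tables print them.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # tiny nudge guards against values like 88.4599999999 that are exactly .5
  # boundaries in exact arithmetic but fell just below in floating point
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}
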