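# Internal helpers shared across the pipeline.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# Named sub-streams derived from one user seed. Fixed offsets per stream so
# adding a new generator never perturbs existing ones. Kept below 2^31.
derive_seed <- function(seed, stream) {
  offsets <- c(
    intensity = 11L, detection = 23L, covariates = 37L, split = 53L,
    run = 71L, external = 89L, noise = 101L
  )
  off <- offsets[[stream]]
  as.integer((as.double(seed) * 127L + off) %% 2147483647)
}

# Round half away from zero (the split's documented rounding rule).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  invisible(x)
}
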