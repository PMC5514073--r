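# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
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

# round-half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# percentage formatting used in reports: one decimal for point estimates,
# integer percent for CI bounds
fmt_pct <- function(p, digits = 1) {
  ifelse(is.na(p), "NA", formatC(100 * p, format = "f", digits = digits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
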