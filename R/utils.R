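# Internal helpers shared across modules.

# Run `fn()` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never perturb user RNG.
seeded <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  fn()
}

# Deterministic per-unit seed derivation from a master seed. Kept inside
# 32-bit integer range whatever the master seed.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1000003 + as.numeric(index)) %% 2147483647)
}

check_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s.",
                  name, deparse(substitute(x))))
  }
  invisible(x)
}

# Composite trapezoid rule on (x, y) pairs.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
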