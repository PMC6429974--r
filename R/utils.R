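# Internal helpers: seed management, quantiles, rounding conventions.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` independent sub-seeds from a master seed. `stream` separates
# independent uses of the same master seed (subjects vs folds vs noise).
# All derived seeds stay below 2^31 - 1.
derive_seeds <- function(seed, n, stream = 0L) {
  base <- (as.numeric(seed) + 7919 * as.numeric(stream)) %% 2147483647
  with_seed(as.integer(base), sample.int(2147483646L, n))
}

# Quantile with SPSS/Minitab plotting positions (linear interpolation of
# order statistics at p(k) = k/(n+1)); used for the cohort median [IQR] table.
quantile6 <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 6, na.rm = TRUE, names = FALSE))
}

# Round to nearest integer with exact halves rounding toward the lower
# (less severe) class -- the package-wide ordinal tie rule.
round_half_down <- function(x) ceiling(x - 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
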