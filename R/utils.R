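# Internal helpers shared across modules.

# Seeded evaluation with a fixed RNG algorithm so that generated datasets are
# reproducible across platforms. Restores the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
    set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  force(code)
}

# Derive a stream-specific child seed from a base seed, keeping the result a
# valid 32-bit integer. `offset` separates independent random streams.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 7919 + offset) %% 2147483647
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper || (!allow_zero_lower && x == lower)) {
    abort(sprintf("`%s` = %g is outside the allowed range [%g, %g].",
                  name, x, lower, upper))
  }
  invisible(x)
}

# Multiplicative lognormal noise with a given coefficient of variation on the
# natural scale: E[factor] = 1, CV[factor] = cv.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Multiplicative Gaussian noise factor (1 + cv * Z).
rnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  1 + rnorm(n, 0, cv)
}
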