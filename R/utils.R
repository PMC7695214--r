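# run expr with a local RNG state seeded by `seed`; the caller's RNG stream
# is left untouched, making every seeded operation a pure function of
# (inputs, seed)
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# k child seeds derived deterministically from one parent seed, all < 2^31
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# truncated normal draws by inverse-CDF; bounds in the same units as mean/sd
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# round half up to integer (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
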