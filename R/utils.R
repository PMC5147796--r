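# Internal helpers: reproducible per-component RNG streams and argument checks.

# Derive a 32-bit sub-seed from a base seed and a component label, so one
# global seed yields independent but reproducible streams per generator.
subSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  ch <- utf8ToInt(stream)
  h <- sum(ch * seq_along(ch)) %% 104729
  as.integer((abs(as.double(seed)) * 48271 + h * 7919 + 12345) %% 2147483647)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

assertScalar <- function(x, name, lower = -Inf, upper = Inf,
                         strictLower = FALSE, strictUpper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  okLo <- if (strictLower) x > lower else x >= lower
  okHi <- if (strictUpper) x < upper else x <= upper
  if (!okLo || !okHi) {
    stop(sprintf("'%s' = %g outside allowed range", name, x), call. = FALSE)
  }
  invisible(x)
}

# Mean of the k smallest values of v, k = ceiling(length(v)/2); the
# lower-half statistic used by the sliding fluorescence baseline.
lowerHalfMean <- function(v) {
  n <- length(v)
  k <- ceiling(n / 2)
  if (k >= n) return(mean(v))
  mean(sort(v, partial = k)[seq_len(k)])
}
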