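#' @include AllClasses.R utils.R
NULL

#' Finite-support discrete power-law and exponential PMFs
#'
#' `discretePowerLawPmf` evaluates `p_alpha(s) = s^alpha / sum_{x=1..N} x^alpha`
#' and `discreteExponentialPmf` evaluates
#' `p_lambda(s) = exp(-lambda s) / sum_{x=1..N} exp(-lambda x)`, both on
#' support `1..nSupport`. These are the two candidate models for avalanche
#' size distributions: a power law up to the system-size cut-off N (the
#' avalanche signature) against the exponential expected for independent
#' activity.
#'
#' @param alpha power-law exponent.
#' @param lambda exponential rate (>= 0).
#' @param nSupport support size N (>= 2).
#' @return Numeric vector of probabilities for s = 1..N (sums to 1).
#' @examples
#' discretePowerLawPmf(-1.5, 3)
#' @export
discretePowerLawPmf <- function(alpha, nSupport) {
  assertScalar(alpha, "alpha")
  if (nSupport < 2) stop("'nSupport' must be >= 2", call. = FALSE)
  x <- seq_len(nSupport)
  p <- x^alpha
  p / sum(p)
}

#' @rdname discretePowerLawPmf
#' @export
discreteExponentialPmf <- function(lambda, nSupport) {
  assertScalar(lambda, "lambda", lower = 0)
  if (nSupport < 2) stop("'nSupport' must be >= 2", call. = FALSE)
  x <- seq_len(nSupport)
  p <- exp(-lambda * x)
  p / sum(p)
}

checkSupport <- function(sizes, nSupport) {
  if (!length(sizes) || length(sizes) < 2) {
    stop("at least 2 sizes required", call. = FALSE)
  }
  if (any(sizes < 1) || any(sizes > nSupport)) {
    stop("all sizes must lie in [1, supportN]; truncate above the cut-off first",
         call. = FALSE)
  }
  invisible(sizes)
}

#' Maximum-likelihood power-law exponent on finite support
#'
#' Maximises `l(alpha | s) = sum_i log p_alpha(s_i)` over
#' `alpha in [alphaRange[1], alphaRange[2]]` for sizes on support
#' `1..supportN`. The likelihood is smooth and unimodal in alpha, so bounded
#' scalar optimisation converges to well below the 1e-4 tolerance contract
#' (a brute-force grid over alpha serves as the test oracle).
#'
#' @param sizes cluster sizes, all within `[1, supportN]` (integer-valued;
#'   truncate sizes above the cut-off first, see [supportSizes()]).
#' @param supportN support size N (electrode count).
#' @param alphaRange search interval (default `c(-6, 0)`).
#' @return A [PowerLawFit-class]. `degenerate = TRUE` flags an optimum pinned
#'   at a search bound (e.g. all sizes equal to 1).
#' @examples
#' fitPowerLawMLE(c(1, 1, 1, 1, 2), supportN = 2)  # alphaHat = -2 exactly
#' @export
fitPowerLawMLE <- function(sizes, supportN, alphaRange = c(-6, 0)) {
  checkSupport(sizes, supportN)
  supportN <- as.integer(supportN)
  n <- length(sizes)
  sumLog <- sum(log(sizes))
  x <- seq_len(supportN)
  logx <- log(x)
  negLL <- function(a) -(a * sumLog - n * log(sum(exp(a * logx))))
  opt <- optimize(negLL, interval = alphaRange, tol = 1e-8)
  aHat <- opt$minimum
  degenerate <- min(aHat - alphaRange[1], alphaRange[2] - aHat) < 1e-4
  if (degenerate) {
    # pick the better bound explicitly (optimize never returns the endpoints)
    bounds <- c(alphaRange[1], alphaRange[2])
    bl <- vapply(bounds, negLL, numeric(1))
    if (min(bl) < opt$objective) {
      aHat <- bounds[which.min(bl)]
      opt$objective <- min(bl)
    }
  }
  new("PowerLawFit", alphaHat = aHat, supportN = supportN,
      logLik = -opt$objective, nSamples = n, degenerate = degenerate)
}

#' Maximum-likelihood exponential rate on finite support
#'
#' Maximises the log-likelihood of `p_lambda` over
#' `lambda in [0, lambdaMax]`; `lambda = 0` corresponds to the uniform
#' distribution on `1..supportN`.
#'
#' @inheritParams fitPowerLawMLE
#' @param lambdaMax upper search bound (default 10).
#' @return An [ExponentialFit-class].
#' @examples
#' fitExponentialMLE(c(1, 2), supportN = 2)  # lambdaHat = 0 (uniform)
#' @export
fitExponentialMLE <- function(sizes, supportN, lambdaMax = 10) {
  checkSupport(sizes, supportN)
  supportN <- as.integer(supportN)
  n <- length(sizes)
  sumS <- sum(sizes)
  x <- seq_len(supportN)
  negLL <- function(l) l * sumS + n * log(sum(exp(-l * x)))
  opt <- optimize(negLL, interval = c(0, lambdaMax), tol = 1e-8)
  lHat <- opt$minimum
  obj <- opt$objective
  # the optimum may sit exactly on the lambda = 0 boundary (uniform data)
  if (negLL(0) <= obj) {
    lHat <- 0
    obj <- negLL(0)
  }
  degenerate <- (lambdaMax - lHat) < 1e-4
  if (degenerate && negLL(lambdaMax) < obj) {
    lHat <- lambdaMax
    obj <- negLL(lambdaMax)
  }
  new("ExponentialFit", lambdaHat = lHat, supportN = supportN,
      logLik = -obj, nSamples = n, degenerate = degenerate)
}

#' Log-likelihood-ratio test: power law versus exponential
#'
#' Fits both models at their MLEs and computes
#' `LLR = l(alphaHat | s) - l(lambdaHat | s)`. Significance uses the
#' Vuong-type normalisation: the statistic
#' `LLR / (sqrt(n) * sd(d_i))`, with `d_i` the per-sample log-likelihood
#' differences, is referred to a two-sided standard normal. A positive LLR
#' with `p < level` favours the power law; a negative one the exponential;
#' otherwise the comparison is undecided (including degenerate data with zero
#' variance of `d_i`).
#'
#' @inheritParams fitPowerLawMLE
#' @param level significance level (default 0.05).
#' @return An [LLRResult-class].
#' @export
llrTest <- function(sizes, supportN, level = 0.05) {
  pl <- fitPowerLawMLE(sizes, supportN)
  ex <- fitExponentialMLE(sizes, supportN)
  lpA <- log(discretePowerLawPmf(alphaHat(pl), supportN))
  lpL <- log(discreteExponentialPmf(lambdaHat(ex), supportN))
  d <- lpA[sizes] - lpL[sizes]
  llr <- sum(d)
  sdD <- sd(d)
  n <- length(sizes)
  if (!is.finite(sdD) || sdD < 1e-12) {
    return(new("LLRResult", llr = llr, pValue = NA_real_,
               favored = "undecided", powerLawFit = pl, exponentialFit = ex))
  }
  z <- llr / (sqrt(n) * sdD)
  p <- 2 * pnorm(-abs(z))
  favored <- if (p >= level) "undecided"
             else if (llr > 0) "power_law"
             else "exponential"
  new("LLRResult", llr = llr, pValue = p, favored = favored,
      powerLawFit = pl, exponentialFit = ex)
}

#' Kolmogorov-Smirnov distance between size distributions
#'
#' `D_KS = max_x | P_data(x) - P_compare(x) |` where `P` are cumulative
#' distributions. The reference may be a power law with a given exponent
#' (e.g. the canonical -1.5 avalanche reference) or a second empirical
#' distribution; in the latter case both are truncated to the shared support
#' `1..min(N1, N2)`.
#'
#' For continuous (uV) distributions pass two [SizeDistribution-class]
#' objects in continuous mode: the comparison is then between empirical CDFs
#' evaluated on the pooled sample points.
#'
#' @param empirical a [SizeDistribution-class] (or numeric vector of discrete
#'   sizes, with `supportN` taken from `referenceN`).
#' @param reference either a single exponent (numeric scalar, reference power
#'   law on the empirical support) or a second [SizeDistribution-class].
#' @param referenceN support for a plain-numeric `empirical` input.
#' @return A [KsDistance-class].
#' @examples
#' sd1 <- sizeDistribution(c(1, 1, 2, 3), supportN = 4)
#' ksDistance(sd1, sd1)            # 0
#' ksDistance(sd1, -1.5)           # vs reference power law
#' @export
ksDistance <- function(empirical, reference, referenceN = NULL) {
  if (is.numeric(empirical)) {
    if (is.null(referenceN)) stop("'referenceN' required for numeric input", call. = FALSE)
    empirical <- sizeDistribution(empirical, supportN = referenceN)
  }
  stopifnot(is(empirical, "SizeDistribution"))
  if (!length(sizes(empirical))) stop("empty distribution", call. = FALSE)

  if (is.numeric(reference) && length(reference) == 1L) {
    nSup <- supportN(empirical)
    s <- sizes(empirical)
    s <- s[s <= nSup]
    if (!length(s)) stop("no sizes within the support", call. = FALSE)
    cdfData <- cumsum(tabulate(s, nbins = nSup)) / length(s)
    cdfRef <- cumsum(discretePowerLawPmf(reference, nSup))
    d <- max(abs(cdfData - cdfRef))
    return(new("KsDistance", dKs = d,
               reference = sprintf("power_law(alpha=%g)", reference)))
  }

  stopifnot(is(reference, "SizeDistribution"))
  if (empirical@mode == "continuous" || reference@mode == "continuous") {
    a <- sizes(empirical); b <- sizes(reference)
    grid <- sort(unique(c(a, b)))
    Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
    Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
    d <- max(abs(Fa - Fb))
    return(new("KsDistance", dKs = d, reference = "empirical (continuous)"))
  }
  nSup <- min(supportN(empirical), supportN(reference))
  a <- sizes(empirical); a <- a[a <= nSup]
  b <- sizes(reference); b <- b[b <= nSup]
  if (!length(a) || !length(b)) stop("no sizes within the shared support", call. = FALSE)
  Fa <- cumsum(tabulate(a, nbins = nSup)) / length(a)
  Fb <- cumsum(tabulate(b, nbins = nSup)) / length(b)
  new("KsDistance", dKs = max(abs(Fa - Fb)), reference = "empirical")
}
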