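# Finite-support discrete power-law / exponential inference.

# independent oracle: brute-force grid maximization of the log-likelihood
gridAlphaMLE <- function(sizes, nSupport, step = 1e-4) {
  grid <- seq(-6, 0, by = step)
  sumLog <- sum(log(sizes))
  n <- length(sizes)
  x <- seq_len(nSupport)
  ll <- grid * sumLog - n * log(vapply(grid, function(a) sum(x^a), numeric(1)))
  grid[which.max(ll)]
}

test_that("model PMFs normalize exactly on their support", {
  for (a in c(-3, -1.5, -0.2, 0)) {
    expect_lt(abs(sum(discretePowerLawPmf(a, 32)) - 1), 1e-12)
  }
  for (l in c(0, 0.5, 2)) {
    expect_lt(abs(sum(discreteExponentialPmf(l, 32)) - 1), 1e-12)
  }
})

test_that("power-law PMF matches direct normalization at N = 2 and N = 3", {
  # 1/(1 + 2^-1.5) and friends, evaluated directly
  expect_equal(discretePowerLawPmf(-1.5, 2), c(0.73880, 0.26120), tolerance = 1e-4)
  expect_equal(discretePowerLawPmf(-1.5, 3), c(0.64683, 0.22868, 0.12448),
               tolerance = 1e-4)
  expect_equal(discretePowerLawPmf(0, 4), rep(0.25, 4))
})

test_that("MLE hits the closed-form stationary point on {1,1,1,1,2}, N=2", {
  # d/dq [ln q - 5 ln(1+q)] = 0 with q = 2^alpha gives q = 1/4, alpha = -2
  fit <- fitPowerLawMLE(c(1, 1, 1, 1, 2), 2)
  expect_equal(alphaHat(fit), -2, tolerance = 1e-5)
  expect_false(fit@degenerate)
})

test_that("all-ones data pins the exponent at the lower search bound, flagged", {
  fit <- fitPowerLawMLE(rep(1, 10), 2)
  expect_true(fit@degenerate)
  expect_equal(alphaHat(fit), -6)
})

test_that("exponential MLE is zero (uniform) on {1,2} with N=2 and positive on 1-heavy data", {
  expect_equal(lambdaHat(fitExponentialMLE(c(1, 2), 2)), 0, tolerance = 1e-6)
  heavy <- c(rep(1, 50), rep(2, 10), rep(3, 2))
  expect_gt(lambdaHat(fitExponentialMLE(heavy, 4)), 0.5)
})

test_that("optimizer agrees with the brute-force grid oracle on random datasets", {
  set.seed(20)
  for (i in 1:25) {
    a <- runif(1, -3, -0.5)
    nSup <- sample(c(8, 16, 32), 1)
    s <- sampleDiscretePowerLaw(a, nSup, 500, seed = i)
    fit <- fitPowerLawMLE(s, nSup)
    expect_lt(abs(alphaHat(fit) - gridAlphaMLE(s, nSup)), 2e-4)
  }
})

test_that("exponent and rate are recovered from the samplers", {
  s <- sampleDiscretePowerLaw(-1.5, 32, 1e5, seed = 12)
  expect_equal(alphaHat(fitPowerLawMLE(s, 32)), -1.5, tolerance = 0.02)

  # inverse-CDF exponential sampler as oracle input
  pmf <- discreteExponentialPmf(0.5, 32)
  set.seed(5)
  se <- findInterval(runif(1e5), cumsum(pmf), left.open = TRUE) + 1L
  expect_equal(lambdaHat(fitExponentialMLE(se, 32)), 0.5, tolerance = 0.02)
})

test_that("exponent estimate is nearly unbiased at n = 1e4", {
  ah <- vapply(1:8, function(i) {
    alphaHat(fitPowerLawMLE(sampleDiscretePowerLaw(-1.5, 32, 1e4, seed = 400 + i), 32))
  }, numeric(1))
  expect_lt(abs(mean(ah) + 1.5), 0.02)
})

test_that("LLR favors the generating model with small p", {
  s <- sampleDiscretePowerLaw(-1.5, 32, 5000, seed = 77)
  res <- llrTest(s, 32)
  expect_gt(res@llr, 0)
  expect_lt(res@pValue, 0.001)
  expect_identical(res@favored, "power_law")

  pmf <- discreteExponentialPmf(0.7, 32)
  set.seed(78)
  se <- findInterval(runif(5000), cumsum(pmf), left.open = TRUE) + 1L
  res2 <- llrTest(se, 32)
  expect_lt(res2@llr, 0)
  expect_identical(res2@favored, "exponential")
})

test_that("degenerate data yield an undecided LLR", {
  res <- llrTest(c(2, 2, 2, 2), 4)
  expect_identical(res@favored, "undecided")
})

test_that("KS distance is zero against itself, one for disjoint point masses, bounded and symmetric", {
  d1 <- sizeDistribution(c(1, 1, 2, 3), supportN = 4)
  expect_equal(ksDistance(d1, d1)@dKs, 0)
  pa <- sizeDistribution(rep(1, 5), supportN = 2)
  pb <- sizeDistribution(rep(2, 5), supportN = 2)
  expect_equal(ksDistance(pa, pb)@dKs, 1)
  d2 <- sizeDistribution(c(1, 2, 2, 4), supportN = 4)
  ab <- ksDistance(d1, d2)@dKs
  ba <- ksDistance(d2, d1)@dKs
  expect_equal(ab, ba)
  expect_gte(ab, 0); expect_lte(ab, 1)
})

test_that("sampler converges to the reference power law in KS distance", {
  s <- sampleDiscretePowerLaw(-1.5, 32, 1e5, seed = 99)
  d <- sizeDistribution(s, supportN = 32)
  expect_lt(ksDistance(d, -1.5)@dKs, 0.01)
})

test_that("sizes outside the support are rejected by the fitters", {
  expect_error(fitPowerLawMLE(c(1, 2, 40), 32), "truncate")
  expect_error(fitPowerLawMLE(c(0, 1), 32), "truncate")
})
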