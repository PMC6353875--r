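test_that("isotherm reproduces hand-derived values and limiting cases", {
  expect_equal(isotherm(0, 0.1, 0.3, 1), 0)
  # quadratic-root oracle: (0.5 - sqrt(0.21)) / 0.2
  expect_equal(isotherm(0.1, 0.1, 0.3, 1), (0.5 - sqrt(0.21)) / 0.2)
  expect_equal(isotherm(0.1, 0.1, 0.3, 1), 0.2087122, tolerance = 1e-6)
  # stoichiometric tight-binding limit: L = 2P, kd -> 0 saturates
  expect_equal(isotherm(0.2, 0.1, 1e-12, 1), 1, tolerance = 1e-5)
  expect_error(isotherm(0.1, 0, 0.3, 1), "P")
  expect_error(isotherm(-0.1, 0.1, 0.3, 1), "L")
  expect_error(isotherm(0.1, 0.1, -0.3, 1), "kd")
})

test_that("isotherm equals the numerically solved quadratic root on random draws", {
  # x^2 - (L+P+kd) x + L P = 0, smaller root x = [PL]; dd = ddmax x / P
  set.seed(101)
  worst <- 0
  for (i in 1:10000) {
    L <- runif(1, 0, 10); P <- runif(1, 0.01, 1)
    kd <- runif(1, 0.01, 10); ddmax <- runif(1, 0.01, 1)
    root <- polyroot(c(L * P, -(L + P + kd), 1))
    ref <- ddmax * min(Re(root)) / P
    worst <- max(worst, abs(isotherm(L, P, kd, ddmax) - ref) /
                   max(abs(ref), .Machine$double.eps))
  }
  expect_lt(worst, 1e-10)
})

test_that("isotherm approaches the hyperbolic form as P -> 0", {
  kd <- 0.3
  P <- 1e-9 * kd
  L <- c(0.01, 0.1, 0.3, 1, 3)
  expect_equal(isotherm(L, P, kd, 0.2), 0.2 * L / (L + kd),
               tolerance = 1e-6)
})

test_that("isotherm is strictly increasing in L and strictly decreasing in kd", {
  L <- seq(0.01, 5, length.out = 200)
  v <- isotherm(L, 0.1, 0.3, 0.2)
  expect_true(all(diff(v) > 0))
  kds <- seq(0.05, 5, length.out = 200)
  v2 <- vapply(kds, function(k) isotherm(0.5, 0.1, k, 0.2), numeric(1))
  expect_true(all(diff(v2) < 0))
})

test_that("fitResidue recovers noiseless truth and matches a log-grid search oracle", {
  kd <- 0.3; ddmax <- 0.2; P <- 0.1
  L <- c(0, 1, 2, 4, 8, 16, 32) * P
  shifts <- forwardShifts(L, P, kd, ddmax = ddmax, theta = 0.7)
  ser <- makeSeries(shifts, L = L, P = P)
  x <- computeCSPs(ser)
  fit <- fitResidue(x, x@residue[1])
  expect_true(fit@converged)
  expect_equal(fit@kd, 0.3, tolerance = 1e-6)
  expect_equal(fit@ddmax, 0.2, tolerance = 1e-6)

  # brute-force 500x500 log-grid oracle over (kd, ddmax)
  y <- x@csp[1, ]
  gridKd <- exp(seq(log(0.01), log(10), length.out = 500))
  gridDd <- exp(seq(log(0.01), log(1), length.out = 500))
  sse <- outer(gridKd, gridDd, Vectorize(function(k, d)
    sum((y - isotherm(L, P, k, d))^2)))
  best <- arrayInd(which.min(sse), dim(sse))
  # fitted optimum within one grid cell of the grid optimum
  stepKd <- log(gridKd[2]) - log(gridKd[1])
  stepDd <- log(gridDd[2]) - log(gridDd[1])
  expect_lt(abs(log(fit@kd) - log(gridKd[best[1]])), stepKd * 1.5)
  expect_lt(abs(log(fit@ddmax) - log(gridDd[best[2]])), stepDd * 1.5)
})

test_that("saturation flags follow the fraction bound at the final point", {
  P <- 0.1
  L <- c(0, 0.5, 1, 2) * P          # only to 2:1 with kd = 5 mM truth
  shifts <- forwardShifts(L, P, kd = 5, ddmax = 0.2, theta = 0.3)
  ser <- makeSeries(shifts, L = L, P = P)
  fit <- fitResidue(computeCSPs(ser), 101L)
  # truth: frac bound at end = isotherm(0.2, 0.1, 5, 1) ~ 0.037 << 0.8
  expect_false(fit@saturated)
  expect_lt(fit@fracBoundEnd, 0.1)

  Lsat <- c(0, 1, 2, 4, 8, 16, 32) * P
  shifts <- forwardShifts(Lsat, P, kd = 0.3, ddmax = 0.2, theta = 0.3)
  fitS <- fitResidue(computeCSPs(makeSeries(shifts, L = Lsat, P = P)), 101L)
  expect_true(fitS@saturated)
})

test_that("fitting requires at least three non-apo points with defined CSP", {
  P <- 0.1; L <- c(0, 0.1, 0.4) * 1
  shifts <- forwardShifts(L, P, 0.3, 0.2, 0.3)
  x <- computeCSPs(makeSeries(shifts, L = L, P = P))
  expect_error(fitResidue(x, 101L), ">= 3 non-apo")
  expect_error(fitResidue(x, 999L), "not in experiment")
})

test_that("aggregation applies the one-pass 2-SD exclusion exactly as hand-computed", {
  fits <- S4Vectors::DataFrame(
    residue = 1:6, kd = c(rep(0.3, 5), 10), kdStderr = 0.01,
    ddmax = 0.2, converged = TRUE, saturated = TRUE, fracBoundEnd = 0.9)
  g <- aggregateGlobalKd(fits)
  # mean 1.9167, SD 3.9600, 2SD 7.9199; |10 - 1.9167| = 8.0833 >= 2SD
  expect_false(g@isLowerLimit)
  expect_equal(g@residuesExcluded, 6L)
  expect_equal(g@meanKd, 0.3)
  expect_equal(g@sdKd, 0)
  expect_equal(length(g@residuesUsed), 5L)
})

test_that("an all-equal Kd population excludes nobody", {
  fits <- S4Vectors::DataFrame(
    residue = 1:4, kd = rep(0.4, 4), kdStderr = 0.01, ddmax = 0.2,
    converged = TRUE, saturated = TRUE, fracBoundEnd = 0.9)
  g <- aggregateGlobalKd(fits)
  expect_equal(g@meanKd, 0.4)
  expect_equal(g@sdKd, 0)
  expect_length(g@residuesExcluded, 0)
})

test_that("mostly-unsaturated fits trigger the lower-limit form '> min Kd'", {
  fits <- S4Vectors::DataFrame(
    residue = 1:4, kd = c(2.0, 2.5, 0.9, 3.0), kdStderr = 0.1,
    ddmax = 0.2, converged = TRUE,
    saturated = c(FALSE, FALSE, TRUE, FALSE), fracBoundEnd = 0.4)
  g <- aggregateGlobalKd(fits)
  expect_true(isLowerLimit(g))
  expect_equal(g@limitValue, 0.9)
  expect_true(is.na(g@meanKd))
  expect_equal(formatGlobalKd(g), "> 0.9 mM")
})

test_that("aggregation needs at least two converged significant fits", {
  fits <- S4Vectors::DataFrame(
    residue = 1:3, kd = c(0.3, 0.4, 0.5), kdStderr = 0.01, ddmax = 0.2,
    converged = c(TRUE, FALSE, FALSE), saturated = TRUE,
    fracBoundEnd = 0.9)
  expect_error(aggregateGlobalKd(fits), "at least 2")
  fits$converged <- TRUE
  expect_error(aggregateGlobalKd(fits, significant = 1L), "at least 2")
  expect_s4_class(aggregateGlobalKd(fits, significant = 1:2), "GlobalKd")
})
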