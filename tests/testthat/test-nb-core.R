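test_that("count datasets validate their invariants", {
  expect_error(countData(c(1, -1), matrix(0, 2, 1)), "nonnegative")
  expect_error(countData(c(1, 2), matrix(0, 3, 1)), "row count")
  expect_error(countData(c(1, 2), cbind(1, c(0.5, 1))), "intercept")
  d <- countData(c(0L, 3L), matrix(c(0.5, -1), 2, 1), offset = 2)
  expect_equal(designMatrix(d)[, 1], c(1, 1))
  expect_equal(offsets(d), c(2, 2))
})

test_that("the linear predictor is K beta + phi + offset", {
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  d <- countData(rep(1L, 4), X, offset = c(0, 0, 0, 0))
  expect_equal(linearPredictor(d, rep(0, 4)), rep(0, 4))
  expect_equal(plogis(linearPredictor(d, rep(0, 4))), rep(0.5, 4))

  # a population offset of 2x the rate base adds log 2 everywhere
  d2 <- countData(rep(1L, 4), X, offset = rateOffset(rep(2e5, 4), per = 1e5))
  beta <- rnorm(4)
  expect_equal(
    linearPredictor(d2, beta),
    linearPredictor(d, beta) + log(2)
  )

  # direct recomputation oracle on a random instance
  phi <- rnorm(4)
  expect_equal(
    linearPredictor(d2, beta, phi),
    drop(cbind(1, X) %*% beta) + phi + log(2)
  )
  expect_error(linearPredictor(d, rep(0, 3)), "length")
})

test_that("the NB log-pmf has the stated closed forms, normalization, and mean", {
  expect_equal(nbLogPmf(0, 0, 1), log(0.5))
  expect_equal(nbLogPmf(0, -40, 1), 0, tolerance = 1e-10)
  # normalization at moderate eta, r
  expect_equal(sum(exp(nbLogPmf(0:2000, 0.5, 1.3))), 1, tolerance = 1e-8)
  # psi is monotone in eta, and so is the pmf mass above any count
  expect_true(all(diff(plogis(seq(-3, 3, 0.1))) > 0))
  # mean identity r * exp(eta), checked by simulation
  set.seed(2)
  y <- rnbinom(1e5, size = 1, prob = plogis(-0.3))
  se <- sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - exp(0.3)), 3 * se)
  expect_error(nbLogPmf(-1, 0, 1), "nonnegative")
  expect_error(nbLogPmf(1, 0, -1), "positive")
})

test_that("Polya-Gamma draws have the analytic mean and variance", {
  pgMean <- function(b, c) if (c == 0) b / 4 else (b / (2 * c)) * tanh(c / 2)
  pgVar <- function(b, c) {
    if (c == 0) return(b / 24)
    (b / (4 * c^3)) * (sinh(c) - c) / cosh(c / 2)^2
  }
  set.seed(3)
  for (bc in list(c(1, 0), c(3, 0), c(2, 1.5))) {
    x <- rPolyaGamma(2e4, bc[1], bc[2])
    expect_true(all(x > 0))
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - pgMean(bc[1], bc[2])), 4 * se)
    expect_equal(var(x), pgVar(bc[1], bc[2]), tolerance = 0.05)
  }
  expect_error(rPolyaGamma(1, 0), "positive")
  expect_error(rPolyaGamma(1, 1, Inf), "finite")

  # latent block: kappa is (y - r)/2 and omega positive
  d <- countData(c(0L, 4L), matrix(c(0.1, 0.2), 2, 1))
  l <- samplePGLatents(d, c(0, 0.5), r = 1.5)
  expect_equal(l$kappa, (c(0, 4) - 1.5) / 2)
  expect_true(all(l$omega > 0))
  expect_error(samplePGLatents(d, c(NaN, 0), 1), "non-finite")
})

test_that("CRT draws are zero at y = 0 and match the digamma mean identity", {
  expect_equal(rCRT(rep(0L, 10), 2), rep(0L, 10))
  set.seed(4)
  x <- rCRT(rep(6L, 2e4), 2)
  m <- 2 * (digamma(8) - digamma(2))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - m), 3 * se)
})

test_that("the coefficient draw matches a directly assembled Gaussian conditional", {
  set.seed(5)
  n <- 6
  X <- cbind(1, matrix(rnorm(n * 2), n, 2))
  d <- countData(rpois(n, 2), X[, -1])
  omega <- runif(n, 0.5, 2)
  kappa <- (counts(d) - 1) / 2
  phi <- rnorm(n, sd = 0.3)
  pv <- c(100, 4, 9)

  P <- crossprod(X * omega, X) + diag(1 / pv)
  Sig <- solve(P)
  mu <- drop(Sig %*% crossprod(X, kappa - omega * phi))

  draws <- t(replicate(2e4, sampleCoefficients(d, omega, unname(kappa), phi, pv)))
  seMean <- sqrt(diag(Sig) / nrow(draws))
  expect_true(all(abs(colMeans(draws) - mu) < 5 * seMean))
  expect_equal(unname(cov(draws)), Sig, tolerance = 0.1)

  # excluded coordinates come back as exact zeros
  one <- sampleCoefficients(d, omega, unname(kappa), phi, pv,
    include = c(TRUE, FALSE, TRUE))
  expect_identical(one[2], 0)
  expect_error(
    sampleCoefficients(d, omega, unname(kappa), phi, pv,
      include = c(FALSE, TRUE, TRUE)),
    "intercept"
  )
})

test_that("with an empty likelihood the coefficient draw returns the prior", {
  # n = 0 rows: the precision collapses to the prior precision
  X <- matrix(numeric(0), 0, 2)
  pv <- c(100, 2.25)
  set.seed(6)
  draws <- t(replicate(2e4, drop(spanbvs:::.cpp_sample_beta(
    X, numeric(0), numeric(0), numeric(0), pv, c(1L, 1L)
  ))))
  expect_equal(apply(draws, 2, var), pv, tolerance = 0.06)
  expect_lt(max(abs(colMeans(draws))), 4 * sqrt(max(pv) / nrow(draws)))
})
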