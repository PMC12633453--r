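test_that("queen lattices have the degrees the contiguity rule forces", {
  g <- queenGrid(2, 2) # complete graph on four cells
  expect_equal(nNodes(g), 4L)
  expect_equal(unname(degrees(g)), rep(3L, 4))
  expect_equal(nrow(graphEdges(g)), 6L)

  g <- queenGrid(10, 5)
  expect_equal(nNodes(g), 50L)
  d <- unname(degrees(g))
  expect_equal(sum(d == 3L), 4L) # corners
  expect_equal(sum(d == 8L), 8L * 3L) # interior cells
  expect_equal(sum(d == 5L), 50L - 4L - 24L) # non-corner border cells

  g <- queenGrid(1, 3) # degenerates to a path
  expect_equal(unname(degrees(g)), c(1L, 2L, 1L))

  expect_error(queenGrid(1, 1), "single-cell")
})

test_that("edge-list graphs deduplicate pairs and reject bad input", {
  g <- graphFromEdges(rbind(c("A", "B"), c("B", "A")), c("A", "B"))
  expect_equal(nrow(graphEdges(g)), 1L)
  expect_equal(unname(degrees(g)), c(1L, 1L))

  g <- graphFromEdges(rbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
  expect_equal(unname(degrees(g)), c(1L, 2L, 1L))

  expect_error(graphFromEdges(rbind(c("A", "A")), c("A", "B")), "self-pairs")
  expect_error(graphFromEdges(rbind(c("A", "Z")), c("A", "B")), "unknown node label")
})

test_that("ICAR precision is D - W with zero row sums and PD after the nugget", {
  path2 <- graphFromEdges(rbind(c("a", "b")), c("a", "b"))
  ic <- icarPrecision(path2)
  expect_equal(unname(ic@Q), rbind(c(1, -1), c(-1, 1)))

  set.seed(4)
  g <- queenGrid(4, 6)
  ic <- icarPrecision(g, nugget = 1e-8)
  expect_true(all(rowSums(ic@Q) == 0))
  ev <- eigen(ic@Q + ic@nugget * diag(nNodes(g)), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-8 * (1 - 1e-6))
  expect_equal(ic@rankDeficiency, 1L)

  # two disconnected blocks: rank deficiency equals the component count
  pairs <- rbind(c("a", "b"), c("c", "d"))
  g2 <- graphFromEdges(pairs, c("a", "b", "c", "d"))
  expect_equal(nComponents(g2), 2L)
  expect_equal(icarPrecision(g2)@rankDeficiency, 2L)
})

test_that("ICAR field draws match the centred inverse-precision law", {
  g <- queenGrid(1, 3)
  ic <- icarPrecision(g)
  nu <- 0.5
  n <- nNodes(g)
  S0 <- solve(nu * ic@Q + ic@nugget * diag(n))
  C <- diag(n) - matrix(1 / n, n, n)
  Sc <- C %*% S0 %*% C

  set.seed(7)
  X <- rICARField(ic, nu, nDraws = 4e4)
  expect_lt(max(abs(rowSums(X))), 1e-10)
  # entrywise agreement within 6 Monte-Carlo SEs (Gaussian 4th-moment SE)
  se <- sqrt((outer(diag(Sc), diag(Sc)) + Sc^2) / nrow(X))
  expect_true(all(abs(cov(X) - Sc) < 6 * se))
  # zero mean within 4 SEs
  expect_true(all(abs(colMeans(X)) < 4 * sqrt(diag(Sc) / nrow(X))))

  # doubling nu halves the variance of any fixed contrast
  set.seed(8)
  X2 <- rICARField(ic, 2 * nu, nDraws = 4e4)
  v1 <- var(X[, 1] - X[, 3])
  v2 <- var(X2[, 1] - X2[, 3])
  expect_equal(v1 / v2, 2, tolerance = 0.1)

  expect_error(rICARField(ic, -1), "positive")
})

test_that("the spatial-field conditional matches a directly assembled Gaussian", {
  g <- queenGrid(1, 3)
  ic <- icarPrecision(g)
  set.seed(10)
  omega <- c(0.8, 1.3, 0.5)
  y <- c(2L, 0L, 5L)
  r <- 1.2
  kappa <- (y - r) / 2
  cvec <- c(0.3, -0.1, 0.6) # non-spatial part of eta
  nu <- 0.7

  # dense oracle, built independently of the sampler code
  n <- 3
  P <- nu * ic@Q + ic@nugget * diag(n) + diag(omega)
  Sig <- solve(P)
  mu <- Sig %*% (kappa - omega * cvec)
  C <- diag(n) - matrix(1 / n, n, n)
  muC <- drop(C %*% mu)
  SigC <- C %*% Sig %*% C

  draws <- t(replicate(3e4, samplePhi(ic, nu, omega, kappa, cvec)))
  expect_lt(max(abs(rowSums(draws))), 1e-10)
  seMean <- sqrt(diag(SigC) / nrow(draws))
  expect_true(all(abs(colMeans(draws) - muC) < 5 * seMean))
  seCov <- sqrt((outer(diag(SigC), diag(SigC)) + SigC^2) / nrow(draws))
  expect_true(all(abs(cov(draws) - SigC) < 6 * seCov))

  # overwhelming smoothing precision pins the field to zero
  big <- replicate(50, samplePhi(ic, 1e8, omega, kappa, cvec))
  expect_lt(max(abs(big)), 1e-2)

  expect_error(samplePhi(ic, nu, omega, kappa, c(Inf, 0, 0)), "non-finite")
})

test_that("the ICAR precision-multiplier update follows its conjugate Gamma law", {
  g <- queenGrid(2, 3)
  ic <- icarPrecision(g)
  n <- nNodes(g)

  # phi = 0: the quadratic form vanishes and nu ~ Gamma(a + (n-1)/2, b)
  set.seed(11)
  draws <- replicate(5000, sampleNu(rep(0, n), ic, aNu = 0.1, bNu = 0.1))
  ks <- suppressWarnings(
    ks.test(draws, pgamma, shape = 0.1 + (n - 1) / 2, rate = 0.1)
  )
  expect_lt(unname(ks$statistic), 0.03)

  # scaling phi by 2 quadruples the rate term and lowers the posterior mean
  phi <- rICARField(ic, 1)
  d1 <- replicate(3000, sampleNu(phi, ic))
  d2 <- replicate(3000, sampleNu(2 * phi, ic))
  expect_gt(mean(d1), mean(d2))
  q1 <- drop(crossprod(phi, ic@Q %*% phi))
  expect_equal(
    drop(crossprod(2 * phi, ic@Q %*% (2 * phi))), 4 * q1,
    tolerance = 1e-12
  )

  expect_error(sampleNu(phi + 1, ic), "sum-to-zero")
})
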