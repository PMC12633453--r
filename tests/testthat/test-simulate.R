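test_that("AR(1) features have the stated 0.1-scaled covariance", {
  set.seed(1)
  x <- arFeatures(1e4, 5, rho = 0)
  expect_equal(unname(apply(x, 2, var)), rep(0.1, 5), tolerance = 0.05)
  cors <- cor(x)[upper.tri(diag(5))]
  expect_lt(max(abs(cors)), 0.05)

  x <- arFeatures(1e4, 6, rho = 0.5)
  c2 <- mean(sapply(1:4, function(j) cor(x[, j], x[, j + 2])))
  expect_equal(c2, 0.25, tolerance = 0.05) # lag-2 correlation rho^2

  # entrywise law-of-large-numbers check against 0.1 * Sigma
  x <- arFeatures(1e5, 4, rho = 0.4)
  Sigma <- 0.1 * 0.4^abs(outer(1:4, 1:4, "-"))
  expect_lt(max(abs(cov(x) - Sigma) / Sigma[1, 1]), 0.05)
  expect_error(arFeatures(10, 3, rho = 1), "below 1")
})

test_that("grouped features are block-correlated and independent across groups", {
  set.seed(2)
  gf <- groupedFeatures(1e4, c(2, 2), rho = 0.5)
  x <- gf$features
  expect_equal(cor(x[, 1], x[, 2]), 0.5, tolerance = 0.05)
  expect_equal(cor(x[, 3], x[, 4]), 0.5, tolerance = 0.05)
  expect_lt(abs(cor(x[, 1], x[, 3])), 0.05)
  expect_equal(as.vector(groupSizes(gf$groups)), c(2, 2))

  # the preset layout for p - 1 = 14 is five, five, four
  expect_equal(spanbvs:::.presetGroupSizes(14), c(5, 5, 4))

  # a single group reduces to the AR(1) generator's law
  g1 <- groupedFeatures(5e3, 4, rho = 0.3)
  expect_equal(dim(g1$features), c(5e3, 4))
  expect_equal(nGroups(g1$groups), 1L)
})

test_that("equicorrelated singletons hit the requested pairwise correlation", {
  set.seed(3)
  x <- equicorrFeatures(1e4, 3, rho = 0.5)
  cors <- cor(x)[upper.tri(diag(3))]
  expect_equal(unname(cors), rep(0.5, 3), tolerance = 0.05)

  x0 <- equicorrFeatures(5e3, 3, rho = 0)
  expect_lt(max(abs(cor(x0)[upper.tri(diag(3))])), 0.06)

  # exchangeable-covariance spectrum: 0.1(1 - rho) and 0.1(1 + (m-1) rho)
  m <- 4; rho <- 0.3
  Sigma <- 0.1 * ((1 - rho) * diag(m) + rho)
  ev <- eigen(Sigma, only.values = TRUE)$values
  expect_equal(sort(unique(round(ev, 10))), sort(c(0.1 * (1 - rho), 0.1 * (1 + (m - 1) * rho))))
  expect_true(all(ev > 0))
  expect_error(equicorrFeatures(10, 3, rho = -0.6), "rho must lie")
})

test_that("sim1 presets match the stated design", {
  st <- simulateScenario("sim1", n = 50, p = 50, rho = 0.25, nu = 0.25, seed = 4)
  expect_equal(nNodes(studyGraph(st)), 50L)
  expect_equal(sum(truthBeta(st) == 2), 10)
  expect_equal(sum(truthSupport(st)), 10)
  expect_equal(truthBeta(st)[1], 0) # intercept truth is zero
  expect_lt(abs(sum(truthPhi(st))), 1e-10)
  expect_null(studyGroups(st))

  # bit-identical regeneration under the same seed
  st2 <- simulateScenario("sim1", n = 50, p = 50, rho = 0.25, nu = 0.25, seed = 4)
  expect_identical(counts(studyData(st)), counts(studyData(st2)))
  expect_identical(designMatrix(studyData(st)), designMatrix(studyData(st2)))
  expect_identical(truthPhi(st), truthPhi(st2))

  # NB outcomes at r = 1 are overdispersed
  y <- counts(studyData(st))
  expect_gt(var(y), mean(y))
})

test_that("sim2 presets activate groups as configured and carry no spatial field", {
  st <- simulateScenario("sim2", n = 100, p = 50, rho = 0.5, case = "full", seed = 5)
  expect_null(studyGraph(st))
  expect_true(all(truthPhi(st) == 0))
  expect_equal(sum(truthSupport(st)), 10)
  b <- truthBeta(st)[-1]
  expect_true(all(b[truthSupport(st)] >= 0.5 & b[truthSupport(st)] <= 2))
  # full case: the ten signals fill exactly two complete groups of five
  act <- unique(groupOf(studyGroups(st))[truthSupport(st)])
  expect_equal(length(act), 2L)
  sizes <- groupSizes(studyGroups(st))
  expect_true(all(sizes[act] == 5))

  stp <- simulateScenario("sim2", n = 100, p = 50, case = "partial", seed = 6)
  tab <- table(groupOf(studyGroups(stp))[truthSupport(stp)])
  expect_equal(sort(as.vector(tab)), c(3, 3, 4))

  expect_error(simulateScenario("sim2", n = 100, p = 50, nu = 0.1, seed = 1),
    "no spatial random effect")
})

test_that("sim3 splits ten effect-4 signals evenly over grouped and singleton halves", {
  st <- simulateScenario("sim3", n = 100, p = 50, nu = 0.1, case = "full", seed = 7)
  expect_equal(sum(truthSupport(st)), 10)
  expect_true(all(truthBeta(st)[-1][truthSupport(st)] == 4))
  gl <- groupOf(studyGroups(st))
  single <- isSingleton(studyGroups(st))
  expect_equal(sum(truthSupport(st) & !single), 5)
  expect_equal(sum(truthSupport(st) & single), 5)
  expect_equal(sum(!single), 25) # first p/2 features grouped in fives
  expect_equal(sum(single), 24)
  expect_false(is.null(studyGraph(st)))

  # full case: the grouped half's signals fill one whole group
  act <- unique(gl[truthSupport(st) & !single])
  expect_equal(length(act), 1L)

  stp <- simulateScenario("sim3", n = 100, p = 50, case = "partial", seed = 8)
  actp <- table(groupOf(studyGroups(stp))[truthSupport(stp) & !isSingleton(studyGroups(stp))])
  expect_equal(sort(as.vector(actp)), c(2, 3))

  expect_error(simulateScenario("sim3", n = 100, p = 52, seed = 1), "divisible")
  expect_error(simulateScenario("sim1", n = 30, p = 50, seed = 1), "grid")
  expect_error(simulateScenario("sim1", n = 50, p = 8, seed = 1), "p >= 11")
})
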