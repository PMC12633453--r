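test_that("PIPs are columnwise frequencies of binary draws", {
  m <- cbind(a = c(1L, 0L, 1L, 1L), b = c(0L, 0L, 0L, 0L))
  expect_equal(pip(m), c(a = 0.75, b = 0))
  expect_error(pip(cbind(c(0.5, 1))), "binary")

  set.seed(1)
  big <- matrix(rbinom(5000, 1, 0.37), 500, 10)
  expect_equal(pip(big), colSums(big) / nrow(big)) # counting oracle
  expect_true(all(pip(big) >= 0 & pip(big) <= 1))
})

test_that("equal-tailed intervals are the stated empirical quantiles", {
  set.seed(2)
  x <- matrix(rnorm(2e4), 1e4, 2)
  ci <- credibleIntervals(x, level = 0.95)
  expect_equal(unname(ci[1, ]), quantile(x[, 1], c(0.025, 0.975), names = FALSE))
  expect_equal(unname(ci[, 1]), rep(-1.96, 2), tolerance = 0.05)
  expect_equal(unname(ci[, 2]), rep(1.96, 2), tolerance = 0.05)

  const <- matrix(3, 200, 1)
  expect_equal(unname(credibleIntervals(const)[1, ]), c(3, 3))
  expect_error(credibleIntervals(matrix(0, 50, 1)), "100 draws")
})

test_that("the ETI zero-exclusion level scores features as the normal oracle predicts", {
  set.seed(3)
  pos <- matrix(abs(rnorm(5000)) + 0.01, ncol = 1)
  expect_equal(unname(etiExclusionLevel(pos)), 0.999)

  sym <- matrix(rnorm(5000), ncol = 1)
  expect_equal(unname(etiExclusionLevel(sym)), 0)

  # N(2, 1): excludes zero up to the level where the lower quantile hits 0,
  # i.e. 1 - 2 * pnorm(-2) ~ 0.954
  shifted <- matrix(rnorm(2e5, mean = 2), ncol = 1)
  expect_equal(unname(etiExclusionLevel(shifted)), 1 - 2 * pnorm(-2),
    tolerance = 0.01)
})

test_that("AUC equals the pairwise-concordance count with ties at half", {
  sc <- c(5, 4, 3, 2, 1)
  truth <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(rocAuc(sc, truth)$auc, 1)
  expect_equal(rocAuc(rep(1, 5), truth)$auc, 0.5)

  set.seed(4)
  for (i in 1:5) {
    scores <- sample(round(rnorm(30), 1)) # coarse grid forces ties
    tr <- runif(30) < 0.4
    if (!any(tr) || all(tr)) next
    expect_equal(rocAuc(scores, tr)$auc, pairwiseAuc(scores, tr))
    # invariance under strictly increasing transforms
    expect_equal(rocAuc(exp(scores), tr)$auc, rocAuc(scores, tr)$auc)
  }
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "positive and")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(40)
  truth <- runif(40) < 0.5
  expect_equal(
    rocAuc(scores, truth)$auc,
    as.numeric(suppressMessages(pROC::auc(pROC::roc(truth, scores,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE))))
  )
})

test_that("selection rules match families and are monotone in the threshold", {
  st <- toyStudy(seed = 6, n = 50, p = 15, rho = 0.25, nu = 0.25)
  fitSS <- fitNBSpatial(studyData(st), spikeSlabPrior(), graph = studyGraph(st),
    nIter = 1200, seed = 7)
  s05 <- selectFeatures(fitSS, pipThreshold = 0.5) # median probability model
  s06 <- selectFeatures(fitSS, pipThreshold = 0.6)
  expect_true(all(s06$selected[s06$selected] %in% s05$selected[s06$selected]))
  expect_true(all(which(s06$selected) %in% which(s05$selected)))
  expect_equal(s05$selected, s05$score >= 0.5) # boundary convention >=
  expect_error(selectFeatures(fitSS, etiLevel = 0.95), "PIPs")

  fitHS <- fitNBSpatial(studyData(st), horseshoePrior(), graph = studyGraph(st),
    nIter = 1200, seed = 7)
  sel <- selectFeatures(fitHS, etiLevel = 0.95)
  ci <- credibleIntervals(fitHS, level = 0.95)
  expect_equal(sel$selected, unname(ci[, 1] > 0 | ci[, 2] < 0))
  expect_error(selectFeatures(fitHS, pipThreshold = 0.5), "no inclusion")
})

test_that("fit evaluation scores against truth and validates feature match", {
  st <- toyStudy(seed = 8, n = 50, p = 15, rho = 0, nu = 0.25)
  fit <- fitNBSpatial(studyData(st), spikeSlabPrior(), graph = studyGraph(st),
    nIter = 1200, seed = 9)
  ev <- evaluateSelection(fit, st)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  expect_equal(ev$auc, rocAuc(pip(fit), truthSupport(st))$auc)
  expect_error(evaluateSelection(fit, c(TRUE, FALSE)), "match")
})
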