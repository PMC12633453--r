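test_that("marginal prior variances follow each family's factorization", {
  # horseshoe: tau^2 lambda_j^2
  v <- priorVariance(horseshoePrior(), list(tau2 = 4, lambda2 = c(9, 1)))
  expect_equal(v, c(36, 4))

  # spike-and-slab: the slab variance for every included coordinate
  v <- priorVariance(spikeSlabPrior(), list(sigma2_slab = 2.5, lambda2 = c(1, 1, 1)))
  expect_equal(v, rep(2.5, 3))

  gs <- groupStructure(c(x1 = "a", x2 = "a", x3 = "solo"))

  # grouped spike-and-slab: zeta^2 tau_g^2, with tau_g pinned to 1 on singletons
  v <- priorVariance(groupedSpikeSlabPrior(gs),
    list(zeta2 = 1.5^2, tau2g = c(4, 7)), featureNames = c("x1", "x2", "x3"))
  expect_equal(unname(v), c(9, 9, 2.25)) # singleton sees zeta^2 = 2.25 only

  # grouped horseshoe: zeta^2 tau_g^2 lambda^2, lambda pinned to 1 on singletons
  v <- priorVariance(groupedHorseshoePrior(gs),
    list(zeta2 = 1, tau2g = c(1, 4), lambda2 = c(1, 1, 99)),
    featureNames = c("x1", "x2", "x3"))
  expect_equal(unname(v[3]), 4) # any lambda value is ignored on the singleton
})

test_that("prior specifications enforce the grouped/ungrouped contract", {
  gs <- groupStructure(c(x1 = "a", x2 = "b"))
  expect_error(groupedHorseshoePrior(NULL), "GroupStructure")
  expect_error(groupedSpikeSlabPrior(groups = NULL), "GroupStructure")
  expect_error(
    new("PriorSpec", family = "hs", hyper = spanbvs:::.defaultHyper(), groups = gs),
    "must not carry"
  )
  expect_error(
    new("PriorSpec", family = "ss",
      hyper = spanbvs:::.defaultHyper(a_omega = -1), groups = NULL),
    "positive"
  )
})

test_that("likelihood-free chains keep singleton-group scales pinned", {
  gs <- groupStructure(c(x1 = "a", x2 = "a", x3 = "solo"))
  ch <- priorSimulation(groupedSpikeSlabPrior(gs), nSweeps = 2000, seed = 1)
  expect_true(all(ch$tau2g[, 2] == 1)) # "solo" is the second factor level
  expect_false(all(ch$tau2g[, 1] == 1))

  gsAllSingle <- groupStructure(c(x1 = "g1", x2 = "g2"))
  ch2 <- priorSimulation(groupedHorseshoePrior(gsAllSingle), nSweeps = 2000, seed = 2)
  expect_true(all(ch2$lambda2_1 == 1))
})

test_that("local scales respond monotonically to coefficient magnitude", {
  ch <- priorSimulation(horseshoePrior(), nFeatures = 3, nSweeps = 2e4, seed = 3)
  # lambda_1 is updated from the beta_1 drawn in the same sweep
  rc <- cor(abs(ch$beta[, 1]), ch$lambda2_1, method = "spearman")
  expect_gt(rc, 0.3)
})

test_that("inclusion indicators follow their prior when the likelihood is absent", {
  ch <- priorSimulation(spikeSlabPrior(fix_omega = 0.3), nFeatures = 5,
    nSweeps = 2e4, seed = 4)
  expect_equal(mean(ch$delta), 0.3, tolerance = 0.02)

  # omega fixed at zero forces every indicator (and coefficient) to zero
  st <- toyStudy(seed = 5, n = 50, p = 15, rho = 0, nu = 0.25)
  fit <- fitNBSpatial(studyData(st), spikeSlabPrior(fix_omega = 0),
    nIter = 400, seed = 6)
  expect_true(all(deltaDraws(fit) == 0L))
  expect_true(all(betaDraws(fit)[, -1] == 0))
  expect_false(any(betaDraws(fit)[, 1] == 0))
})

test_that("a never-included group's scale follows its hyperprior conditional", {
  gs <- groupStructure(setNames(rep(c("a", "b"), each = 2), paste0("x", 1:4)))
  ch <- priorSimulation(groupedSpikeSlabPrior(gs, fix_omega = 0),
    nSweeps = 1e5, thin = 5, seed = 7)
  expect_true(all(ch$delta == 0L))
  # with no included members the tau_g chain must still mix over its
  # half-Cauchy prior marginal
  set.seed(8)
  ks <- suppressWarnings(ks.test(sqrt(ch$tau2g[, 1]), abs(rcauchy(2e4))))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("a loaded group's scale stochastically dominates idle groups'", {
  # two grouped-horseshoe groups; data put all the signal in group one
  set.seed(9)
  n <- 60
  X <- matrix(rnorm(n * 4, sd = 0.5), n, 4)
  colnames(X) <- paste0("x", 1:4)
  eta <- 2 * X[, 1] + 2 * X[, 2]
  y <- rnbinom(n, size = 1, prob = plogis(-eta))
  gs <- groupStructure(c(x1 = "a", x2 = "a", x3 = "b", x4 = "b"))
  fit <- fitNBSpatial(countData(y, X), groupedHorseshoePrior(gs),
    nIter = 4000, seed = 10)
  tg <- fit@groupTraces$tau2g
  expect_gt(mean(tg[, "a"] > tg[, "b"]), 0.6)
  expect_gt(median(tg[, "a"]), median(tg[, "b"]))
})

test_that("group files are read with singleton fallback and overlap rejection", {
  tmp <- withr::local_tempdir()
  gf <- file.path(tmp, "groups.tsv")
  writeLines(c("feature\tgroup", "x1\tA", "x2\tA"), gf)
  expect_warning(gs <- readGroups(gf, c("x1", "x2", "x3")), "singleton")
  expect_equal(nGroups(gs), 2L)
  expect_true(isSingleton(gs)[["x3"]])

  writeLines(c("feature\tgroup", "x1\tA", "x1\tB"), gf)
  expect_error(readGroups(gf, c("x1")), "overlapping")

  # random single-assignment resolves overlaps reproducibly
  tab <- data.frame(feature = c("x1", "x1", "x2"), group = c("A", "B", "B"))
  g1 <- resolveOverlaps(tab, seed = 3)
  g2 <- resolveOverlaps(tab, seed = 3)
  expect_identical(groupOf(g1), groupOf(g2))
  expect_equal(length(groupOf(g1)), 2L)
})
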