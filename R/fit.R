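#' @include priors.R
NULL

#' Fit the spatial negative binomial model by Gibbs sampling
#'
#' Runs the Polya-Gamma augmented Gibbs sampler. Each sweep updates, in fixed
#' order: the Polya-Gamma latents, the coefficients (jointly for continuous
#' priors; collapsed per-coordinate indicator updates followed by a joint
#' refresh of the included set for spike-and-slab families), the shrinkage
#' scales, the spatial field and its precision (when a graph is supplied),
#' and the dispersion (unless fixed). Identical data, configuration, and
#' seed give bit-identical draws.
#'
#' @param data a [CountData].
#' @param prior a [PriorSpec]; grouped families must carry a
#'   [GroupStructure] covering exactly the features of `data`.
#' @param graph optional [SpatialGraph] over the locations of `data`;
#'   supplying one switches the ICAR spatial random effect on.
#' @param nIter total Gibbs sweeps (default 10000).
#' @param burnIn burn-in fraction in (0, 1) (default 0.5).
#' @param thin keep every `thin`-th post-burn-in sweep (default 1).
#' @param seed integer seed; `NULL` leaves the RNG stream untouched (used
#'   when resuming from a checkpoint).
#' @param fixedR optional positive value freezing the dispersion.
#' @param rInit initial dispersion when it is sampled (default 1).
#' @param initState a `finalState` list from a previous [NBFit] to resume a
#'   chain; skips initialization.
#' @param storageCapMb refuse runs whose retained draws would exceed this
#'   many megabytes (default 1024).
#' @param verbose print progress every 500 sweeps.
#' @return an [NBFit].
#' @examples
#' study <- simulateScenario("sim1", n = 50, p = 20, rho = 0, nu = 0.25, seed = 1)
#' fit <- fitNBSpatial(studyData(study), spikeSlabPrior(),
#'   graph = studyGraph(study), nIter = 400, seed = 1)
#' head(pip(fit))
#' @export
fitNBSpatial <- function(data, prior, graph = NULL, nIter = 10000L,
                         burnIn = 0.5, thin = 1L, seed = NULL, fixedR = NULL,
                         rInit = 1, initState = NULL, storageCapMb = 1024,
                         verbose = FALSE) {
  stopifnot(is(data, "CountData"), is(prior, "PriorSpec"))
  n <- nLocations(data)
  p <- ncol(data@design)
  fn <- featureNames(data)
  if (!(burnIn >= 0 && burnIn < 1))
    stop("burnIn must lie in [0, 1); 0 is meant for continuation segments only")
  if (thin < 1L) stop("thin must be at least 1")

  grouped <- prior@family %in% c("grouped_hs", "grouped_ss")
  gi <- if (grouped) .groupIndices(prior@groups, fn) else
    list(group = integer(0), gsize = integer(0), levels = character(0))

  spatial <- !is.null(graph)
  if (spatial) {
    stopifnot(is(graph, "SpatialGraph"))
    if (nNodes(graph) != n)
      stop("graph must cover all locations: ", nNodes(graph), " nodes vs ",
        n, " locations")
    if (!identical(graph@labels, data@labels) &&
      !all(grepl("^loc[0-9]+$", data@labels))) {
      if (!setequal(graph@labels, data@labels))
        stop("graph and data location labels do not match")
      stop("graph nodes are ordered differently from the data locations")
    }
    icar <- icarPrecision(graph, nugget = prior@hyper$nugget)
    Q <- icar@Q
    comp <- as.integer(icar@membership - 1L)
  } else {
    Q <- matrix(0, 0, 0)
    comp <- integer(0)
  }

  S <- floor(nIter * (1 - burnIn) / thin)
  if (S < 1L) stop("configuration retains no draws")
  nBurn <- nIter - S * thin
  storage <- S * (p + n * spatial + (p - 1)) * 8 / 2^20
  if (storage > storageCapMb)
    stop(sprintf("retained draws would need ~%.0f MB; raise storageCapMb or thin", storage))

  hyper <- prior@hyper
  updateR <- is.null(fixedR)
  if (!updateR) {
    if (fixedR <= 0) stop("fixedR must be positive")
    rInit <- fixedR
  }
  if (!is.null(seed)) set.seed(seed)

  res <- .cpp_run_sampler(
    data@counts, data@design, data@offset, Q, comp, spatial,
    .familyCode(prior@family), gi$group, gi$gsize, hyper,
    as.integer(nIter), as.integer(nBurn), as.integer(thin),
    updateR, rInit, initState, verbose
  )

  beta <- res$beta
  colnames(beta) <- colnames(data@design)
  delta <- if (!is.null(res$delta)) res$delta else matrix(0L, 0, p - 1)
  if (nrow(delta) > 0) colnames(delta) <- fn
  phi <- if (!is.null(res$phi)) res$phi else matrix(0, 0, n)
  if (nrow(phi) > 0) colnames(phi) <- data@labels

  tr <- data.frame(r = res$r)
  for (nm in c("nu", "tau2", "zeta2", "sigma2_slab", "omega")) {
    if (!is.null(res[[nm]])) tr[[nm]] <- res[[nm]]
  }
  groupTraces <- list()
  for (nm in c("wg", "tau2g")) {
    if (!is.null(res[[nm]])) {
      colnames(res[[nm]]) <- gi$levels
      groupTraces[[nm]] <- res[[nm]]
    }
  }

  new("NBFit",
    betaDraws = beta, deltaDraws = delta, phiDraws = phi, traces = tr,
    groupTraces = groupTraces, family = prior@family, featureNames = fn,
    labels = data@labels,
    config = list(
      nIter = as.integer(nIter), burnIn = burnIn, thin = as.integer(thin),
      nBurn = nBurn, seed = seed, spatial = spatial, family = prior@family,
      fixedR = fixedR, hyper = hyper,
      groups = if (grouped) groupOf(prior@groups) else NULL,
      resumed = !is.null(initState)
    ),
    finalState = res$state
  )
}

#' Continue a fitted chain from its checkpoint
#'
#' Resumes the Gibbs sampler from the final state stored in `fit` without
#' reseeding, so that (within one R session and RNG stream) running
#' `n1 + n2` sweeps equals running `n1` then resuming for `n2`.
#'
#' @param fit an [NBFit].
#' @param data,prior,graph the objects used for the original fit.
#' @param nIter additional sweeps; all are retained (`burn-in 0`) unless
#'   `burnIn` is given.
#' @param burnIn fraction of the additional sweeps to discard (default 0).
#' @param thin thinning of the additional sweeps.
#' @return an [NBFit] for the continuation segment.
#' @export
resumeFit <- function(fit, data, prior, graph = NULL, nIter, burnIn = 0,
                      thin = 1L) {
  stopifnot(is(fit, "NBFit"))
  fitNBSpatial(data, prior, graph,
    nIter = nIter,
    burnIn = burnIn, thin = thin, seed = NULL, fixedR = fit@config$fixedR,
    initState = fit@finalState
  )
}

#' @describeIn NBFit-class S x p matrix of coefficient draws
#' @param object an `NBFit`
#' @export
setMethod("betaDraws", "NBFit", function(object, ...) object@betaDraws)

#' @describeIn NBFit-class S x (p-1) matrix of inclusion-indicator draws
#' @export
setMethod("deltaDraws", "NBFit", function(object, ...) object@deltaDraws)

#' @describeIn NBFit-class S x n matrix of spatial-field draws
#' @export
setMethod("phiDraws", "NBFit", function(object, ...) object@phiDraws)

#' @describeIn NBFit-class scalar parameter traces (data frame)
#' @export
setMethod("traces", "NBFit", function(object, ...) object@traces)

#' @describeIn NBFit-class non-intercept feature names
#' @export
setMethod("featureNames", "NBFit", function(object, ...) object@featureNames)

setMethod("show", "NBFit", function(object) {
  cat(sprintf(
    "NBFit: family '%s', %d retained draws, %d coefficients%s%s\n",
    object@family, nrow(object@betaDraws), ncol(object@betaDraws),
    if (nrow(object@phiDraws) > 0) {
      sprintf(", spatial field over %d locations", ncol(object@phiDraws))
    } else "",
    if (!is.null(object@config$fixedR)) {
      sprintf(", r fixed at %g", object@config$fixedR)
    } else ""
  ))
})
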