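#' @include spanbvs-package.R
NULL

#' Spatial neighbourhood graph
#'
#' An undirected graph over study locations, stored as a deduplicated edge
#' list of unordered node pairs. Self-loops are disallowed; symmetry is
#' structural. Connected-component membership is precomputed because the
#' ICAR precision matrix built from the graph is rank deficient by exactly
#' the number of components.
#'
#' @slot nNodes number of locations.
#' @slot edges two-column integer matrix of node indices, each row one
#'   unordered edge with `edges[, 1] < edges[, 2]`.
#' @slot labels character vector of node labels.
#' @slot degrees integer vector of neighbour counts.
#' @slot membership integer vector of connected-component ids (1-based).
#' @exportClass SpatialGraph
setClass("SpatialGraph",
  representation(
    nNodes = "integer",
    edges = "matrix",
    labels = "character",
    degrees = "integer",
    membership = "integer"
  )
)

setValidity("SpatialGraph", function(object) {
  n <- object@nNodes
  e <- object@edges
  if (n < 1L) return("nNodes must be positive")
  if (ncol(e) != 2L) return("edges must have two columns")
  if (nrow(e) > 0L) {
    if (any(e[, 1] == e[, 2])) return("self-loops are not allowed")
    if (any(e < 1L) || any(e > n)) return("edge indices out of range")
    if (any(e[, 1] >= e[, 2])) return("edges must be stored with first index < second")
    if (anyDuplicated(e)) return("duplicate edges")
  }
  if (length(object@labels) != n) return("labels length must equal nNodes")
  if (length(object@degrees) != n) return("degrees length must equal nNodes")
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = n)
  if (!identical(as.integer(deg), object@degrees))
    return("degrees inconsistent with edge list")
  if (length(object@membership) != n) return("membership length must equal nNodes")
  TRUE
})

#' ICAR prior structure
#'
#' Holds the intrinsic autoregressive precision structure Q = D - W for a
#' [SpatialGraph], the diagonal nugget added for numerical propriety, and the
#' rank deficiency (one per connected component).
#'
#' @slot Q symmetric positive semi-definite matrix D - W (without nugget).
#' @slot nugget small positive precision added to the diagonal.
#' @slot rankDeficiency number of connected components of the graph.
#' @slot membership component id per node (1-based).
#' @slot labels node labels carried over from the graph.
#' @exportClass ICARPrior
setClass("ICARPrior",
  representation(
    Q = "matrix",
    nugget = "numeric",
    rankDeficiency = "integer",
    membership = "integer",
    labels = "character"
  )
)

setValidity("ICARPrior", function(object) {
  Q <- object@Q
  if (nrow(Q) != ncol(Q)) return("Q must be square")
  if (max(abs(rowSums(Q))) > 1e-10) return("row sums of Q must be zero")
  off <- Q[row(Q) != col(Q)]
  if (any(off > 1e-12) || any(off < -1 - 1e-12))
    return("off-diagonal entries of Q must be 0 or -1")
  if (object@nugget <= 0) return("nugget must be positive")
  if (object@rankDeficiency < 1L) return("rankDeficiency must be at least 1")
  TRUE
})

#' Spatially indexed count dataset
#'
#' Counts, a design matrix whose first column is the intercept, an offset
#' (zero by default; `log(P_i) - log(rate base)` for rate models), and
#' location labels.
#'
#' @slot counts nonnegative integer outcome vector.
#' @slot design numeric design matrix; first column identically one.
#' @slot offset per-location additive offset on the linear predictor.
#' @slot labels location identifiers.
#' @exportClass CountData
setClass("CountData",
  representation(
    counts = "integer",
    design = "matrix",
    offset = "numeric",
    labels = "character"
  )
)

setValidity("CountData", function(object) {
  n <- length(object@counts)
  if (n == 0L) return("no observations")
  if (any(object@counts < 0L)) return("counts must be nonnegative")
  if (nrow(object@design) != n) return("design row count must match counts")
  if (any(object@design[, 1] != 1)) return("first design column must be the intercept (all ones)")
  if (length(object@offset) != n) return("offset length must match counts")
  if (any(!is.finite(object@offset))) return("offset must be finite")
  if (length(object@labels) != n) return("labels length must match counts")
  TRUE
})

#' Feature grouping
#'
#' A partition of the non-intercept features into labelled groups. Groups of
#' size one are singletons; grouped priors drop the redundant hierarchy level
#' for them (the local scale in the grouped horseshoe, the group scale in the
#' grouped spike-and-slab).
#'
#' @slot assignment factor of group labels, one per feature, named by feature.
#' @exportClass GroupStructure
setClass("GroupStructure", representation(assignment = "factor"))

setValidity("GroupStructure", function(object) {
  a <- object@assignment
  if (length(a) == 0L) return("empty group assignment")
  if (is.null(names(a)) || any(names(a) == "") || anyDuplicated(names(a)))
    return("assignment must be named by unique feature names")
  if (anyNA(a)) return("every feature must belong to exactly one group")
  TRUE
})

#' Shrinkage prior specification
#'
#' One of the families `"normal"` (fixed Gaussian prior variance, no
#' selection), `"hs"`, `"ss"`, `"grouped_hs"`, `"grouped_ss"`, plus fixed
#' hyperparameters. Grouped families require a [GroupStructure]; ungrouped
#' families reject one.
#'
#' @slot family prior family string.
#' @slot hyper named list of hyperparameters.
#' @slot groups a [GroupStructure] or `NULL`.
#' @exportClass PriorSpec
setClass("PriorSpec",
  representation(family = "character", hyper = "list", groups = "ANY")
)

setValidity("PriorSpec", function(object) {
  fams <- c("normal", "hs", "ss", "grouped_hs", "grouped_ss")
  if (!(object@family %in% fams))
    return(sprintf("family must be one of %s", paste(fams, collapse = ", ")))
  grouped <- object@family %in% c("grouped_hs", "grouped_ss")
  if (grouped && !is(object@groups, "GroupStructure"))
    return("grouped families require a GroupStructure")
  if (!grouped && !is.null(object@groups))
    return("ungrouped families must not carry a GroupStructure")
  hv <- unlist(object@hyper[vapply(object@hyper, is.numeric, logical(1))])
  hv <- hv[!is.na(hv)]
  if (any(hv <= 0 & names(hv) %in% c(
    "a_omega", "b_omega", "a_slab", "b_slab", "a_nu", "b_nu",
    "a_r", "b_r", "v_intercept", "v_normal", "nugget"
  ))) {
    return("hyperparameters must be strictly positive")
  }
  TRUE
})

#' Posterior draws from the Gibbs sampler
#'
#' Post-burn-in, thinned draws for all stored parameter blocks, plus the
#' final sampler state (for checkpoint/resume) and the configuration used.
#'
#' @slot betaDraws S x p coefficient draws (intercept first).
#' @slot deltaDraws S x (p-1) binary inclusion draws (spike-and-slab
#'   families; zero rows otherwise).
#' @slot phiDraws S x n spatial-effect draws (zero rows if aspatial).
#' @slot traces data frame of scalar traces (always `r`; `nu`, `tau2`,
#'   `zeta2`, `sigma2_slab`, `omega` when present).
#' @slot groupTraces list of per-group trace matrices (`wg`, `tau2g`).
#' @slot family prior family string.
#' @slot featureNames non-intercept feature names.
#' @slot labels location labels.
#' @slot config list recording the sampler configuration and seed.
#' @slot finalState internal sampler state at the last sweep.
#' @exportClass NBFit
setClass("NBFit",
  representation(
    betaDraws = "matrix",
    deltaDraws = "matrix",
    phiDraws = "matrix",
    traces = "data.frame",
    groupTraces = "list",
    family = "character",
    featureNames = "character",
    labels = "character",
    config = "list",
    finalState = "list"
  )
)

setValidity("NBFit", function(object) {
  S <- nrow(object@betaDraws)
  if (S < 1L) return("no retained draws")
  if (nrow(object@traces) != S) return("trace length must match retained draws")
  if (nrow(object@deltaDraws) > 0L && nrow(object@deltaDraws) != S)
    return("delta draws must match retained draws")
  if (nrow(object@phiDraws) > 0L) {
    if (nrow(object@phiDraws) != S) return("phi draws must match retained draws")
    if (max(abs(rowSums(object@phiDraws))) > 1e-8 * max(1, ncol(object@phiDraws)))
      return("every retained spatial field must sum to zero")
  }
  TRUE
})

#' A simulated study with known ground truth
#'
#' @slot data the simulated [CountData].
#' @slot graph the [SpatialGraph] used for the spatial field, or `NULL`.
#' @slot truthBeta true coefficient vector (intercept first).
#' @slot truthSupport logical mask of truly non-null features.
#' @slot truthPhi true spatial field (zeros if no spatial effect).
#' @slot groups [GroupStructure] or `NULL`.
#' @slot config list of generator settings including all seeds.
#' @exportClass SimulatedStudy
setClass("SimulatedStudy",
  representation(
    data = "CountData",
    graph = "ANY",
    truthBeta = "numeric",
    truthSupport = "logical",
    truthPhi = "numeric",
    groups = "ANY",
    config = "list"
  )
)

setValidity("SimulatedStudy", function(object) {
  p <- ncol(object@data@design)
  if (length(object@truthBeta) != p) return("truthBeta length must equal ncol(design)")
  if (length(object@truthSupport) != p - 1L)
    return("truthSupport must cover the non-intercept features")
  if (abs(sum(object@truthPhi)) > 1e-8) return("true spatial field must sum to zero")
  TRUE
})
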