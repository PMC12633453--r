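#' @include AllGenerics.R
NULL

#' Define a feature grouping
#'
#' @param assignment vector (or factor) of group labels, one per feature,
#'   named by feature name.
#' @return a [GroupStructure].
#' @examples
#' gs <- groupStructure(c(x1 = "A", x2 = "A", x3 = "B"))
#' groupSizes(gs)
#' @export
groupStructure <- function(assignment) {
  if (is.null(names(assignment))) stop("assignment must be named by feature")
  new("GroupStructure", assignment = factor(assignment))
}

#' Read a feature-to-group assignment file
#'
#' Two-column delimited text (feature, group) with a mandatory header.
#' Features present in `featureNames` but absent from the file become
#' singleton groups with a warning. A feature listed under more than one
#' group is an error; see [resolveOverlaps()] for random single-assignment.
#'
#' @param path path to a tab- or comma-delimited two-column file.
#' @param featureNames the full ordered feature set of the model.
#' @return a [GroupStructure] covering `featureNames` in order.
#' @export
readGroups <- function(path, featureNames) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, colClasses = "character")
  if (ncol(tab) != 2L) stop("group file must have exactly two columns (feature, group)")
  if (anyDuplicated(tab[[1]])) {
    dup <- unique(tab[[1]][duplicated(tab[[1]])])
    stop("overlapping groups: feature(s) assigned more than once: ",
      paste(dup, collapse = ", "),
      ". Use resolveOverlaps() for random single-assignment.")
  }
  unknown <- setdiff(tab[[1]], featureNames)
  if (length(unknown) > 0L)
    stop("group file names unknown feature(s): ", paste(unknown, collapse = ", "))
  assignment <- setNames(tab[[2]], tab[[1]])[featureNames]
  missing <- featureNames[is.na(assignment)]
  if (length(missing) > 0L) {
    warning(length(missing), " feature(s) absent from the group file were made singletons: ",
      paste(head(missing, 5L), collapse = ", "),
      if (length(missing) > 5L) ", ..." else "")
    assignment[is.na(assignment)] <- paste0(".singleton_", missing)
  }
  names(assignment) <- featureNames
  groupStructure(assignment)
}

#' Resolve overlapping group memberships by random single-assignment
#'
#' When a feature is annotated to several groups (as with gene-ontology
#' terms), assign it to exactly one, chosen uniformly at random under a
#' recorded seed.
#'
#' @param table data frame with columns feature and group (possibly
#'   repeating features).
#' @param seed integer seed recorded with the assignment.
#' @return a [GroupStructure]; the seed is kept in `attr(, "seed")`.
#' @export
resolveOverlaps <- function(table, seed) {
  set.seed(seed)
  table <- table[sample.int(nrow(table)), , drop = FALSE]
  keep <- !duplicated(table[[1]])
  assignment <- setNames(as.character(table[[2]][keep]), table[[1]][keep])
  out <- groupStructure(assignment)
  attr(out, "seed") <- seed
  out
}

#' @describeIn GroupStructure-class group sizes M_g
#' @param object a `GroupStructure`
#' @export
setMethod("groupSizes", "GroupStructure", function(object, ...)
  table(object@assignment))

#' @describeIn GroupStructure-class number of groups G
#' @export
setMethod("nGroups", "GroupStructure", function(object, ...)
  nlevels(object@assignment))

#' @describeIn GroupStructure-class which features form singleton groups
#' @export
setMethod("isSingleton", "GroupStructure", function(object, ...) {
  sizes <- table(object@assignment)
  setNames(as.vector(sizes[object@assignment] == 1L), names(object@assignment))
})

#' @describeIn GroupStructure-class group label of every feature
#' @export
setMethod("groupOf", "GroupStructure", function(object, ...)
  setNames(as.character(object@assignment), names(object@assignment)))

#' @describeIn GroupStructure-class feature names, in model order
#' @export
setMethod("featureNames", "GroupStructure", function(object, ...)
  names(object@assignment))

setMethod("show", "GroupStructure", function(object) {
  sizes <- table(object@assignment)
  cat(sprintf(
    "GroupStructure: %d features in %d groups (%d singleton)\n",
    length(object@assignment), length(sizes), sum(sizes == 1L)
  ))
})

.defaultHyper <- function(...) {
  h <- list(
    a_omega = 1, b_omega = 1, a_slab = 0.5, b_slab = 0.5,
    a_nu = 0.1, b_nu = 0.1, a_r = 1, b_r = 1,
    v_intercept = 100, v_normal = 100, nugget = 1e-8
  )
  dots <- list(...)
  h[names(dots)] <- dots
  h
}

#' Shrinkage prior constructors
#'
#' `horseshoePrior()` places half-Cauchy(0, 1) priors on a global scale tau
#' and per-feature local scales lambda_j, so each coefficient sees variance
#' `tau^2 lambda_j^2`. `spikeSlabPrior()` mixes a point mass at zero with a
#' Gaussian slab `N(0, sigma_slab^2)` through Bernoulli(omega) indicators,
#' `omega ~ Beta(aOmega, bOmega)` and `sigma_slab^2 ~ IG(aSlab, bSlab)`.
#' `groupedHorseshoePrior()` adds a half-Cauchy group scale tau_g and a
#' global-global scale zeta (variance `zeta^2 tau_g^2 lambda_gk^2`; singleton
#' groups pin `lambda = 1`). `groupedSpikeSlabPrior()` is the hybrid: the
#' slab variance factorises as `zeta^2 tau_g^2` with half-Cauchy zeta and
#' tau_g, per-group inclusion fractions `w_g ~ Beta(aOmega, bOmega)`, and
#' singleton groups pin `tau_g^2 = 1`. `normalPrior()` is a non-selecting
#' fixed-variance Gaussian baseline.
#'
#' @param groups a [GroupStructure] (grouped families only).
#' @param aOmega,bOmega Beta hyperparameters of the inclusion fraction(s).
#' @param aSlab,bSlab inverse-gamma hyperparameters of the slab variance
#'   (ungrouped spike-and-slab only).
#' @param variance fixed prior variance of `normalPrior`.
#' @param ... further hyperparameters passed through (e.g. `v_intercept`,
#'   `a_r`, `b_r`, `a_nu`, `b_nu`, `nugget`).
#' @return a [PriorSpec].
#' @name priors
NULL

#' @rdname priors
#' @export
horseshoePrior <- function(...) {
  new("PriorSpec", family = "hs", hyper = .defaultHyper(...), groups = NULL)
}

#' @rdname priors
#' @export
spikeSlabPrior <- function(aOmega = 1, bOmega = 1, aSlab = 0.5, bSlab = 0.5, ...) {
  new("PriorSpec", family = "ss",
    hyper = .defaultHyper(a_omega = aOmega, b_omega = bOmega,
      a_slab = aSlab, b_slab = bSlab, ...),
    groups = NULL)
}

#' @rdname priors
#' @export
groupedHorseshoePrior <- function(groups, ...) {
  new("PriorSpec", family = "grouped_hs", hyper = .defaultHyper(...),
    groups = groups)
}

#' @rdname priors
#' @export
groupedSpikeSlabPrior <- function(groups, aOmega = 1, bOmega = 1, ...) {
  new("PriorSpec", family = "grouped_ss",
    hyper = .defaultHyper(a_omega = aOmega, b_omega = bOmega, ...),
    groups = groups)
}

#' @rdname priors
#' @export
normalPrior <- function(variance = 100, ...) {
  new("PriorSpec", family = "normal",
    hyper = .defaultHyper(v_normal = variance, ...), groups = NULL)
}

# internal: family string -> C++ code
.familyCode <- function(family) {
  match(family, c("normal", "hs", "ss", "grouped_hs", "grouped_ss")) - 1L
}

# internal: 0-based group index vector and sizes, ordered by featureNames
.groupIndices <- function(groups, featureNames) {
  if (is.null(groups)) {
    return(list(group = integer(0), gsize = integer(0), levels = character(0)))
  }
  a <- groups@assignment
  if (!setequal(names(a), featureNames))
    stop("group structure does not cover exactly the model features")
  a <- a[featureNames]
  a <- droplevels(a)
  list(
    group = as.integer(a) - 1L,
    gsize = as.integer(table(a)),
    levels = levels(a)
  )
}

#' Marginal prior variance of each coefficient
#'
#' The Gaussian variance each non-intercept coefficient sees in the current
#' sweep: `tau^2 lambda_j^2` (horseshoe), `sigma_slab^2` (spike-and-slab,
#' for included coordinates), `zeta^2 tau_g^2 lambda_gk^2` (grouped
#' horseshoe, `lambda = 1` on singleton groups), `zeta^2 tau_g^2` (grouped
#' spike-and-slab slab variance, `tau_g = 1` on singleton groups).
#'
#' @param prior a [PriorSpec].
#' @param state named list of the current scale parameters: uses `tau2`,
#'   `lambda2`, `sigma2_slab`, `zeta2`, `tau2g` as the family requires.
#' @param featureNames feature ordering (required for grouped families).
#' @return a positive vector with one entry per non-intercept feature.
#' @export
priorVariance <- function(prior, state, featureNames = NULL) {
  stopifnot(is(prior, "PriorSpec"))
  need <- function(nm) {
    if (is.null(state[[nm]]))
      stop(sprintf("state lacks '%s' required by family '%s'", nm, prior@family))
    state[[nm]]
  }
  switch(prior@family,
    normal = rep(prior@hyper$v_normal, length(featureNames)),
    hs = need("tau2") * need("lambda2"),
    ss = rep(need("sigma2_slab"), length(need("lambda2"))),
    grouped_hs = {
      if (is.null(featureNames)) featureNames <- featureNames(prior@groups)
      gi <- .groupIndices(prior@groups, featureNames)
      g <- gi$group + 1L
      lambda2 <- need("lambda2")
      lambda2[gi$gsize[g] == 1L] <- 1
      need("zeta2") * need("tau2g")[g] * lambda2
    },
    grouped_ss = {
      if (is.null(featureNames)) featureNames <- featureNames(prior@groups)
      gi <- .groupIndices(prior@groups, featureNames)
      g <- gi$group + 1L
      tau2g <- need("tau2g")
      tau2g[gi$gsize == 1L] <- 1
      need("zeta2") * tau2g[g]
    }
  )
}

#' Likelihood-free Gibbs chain on the prior
#'
#' Alternates coefficient draws from their conditional prior with the same
#' scale/indicator updates the posterior sampler uses, so the stationary law
#' is the joint prior of the chosen family. Used to verify that the Gibbs
#' updates reproduce the stated half-Cauchy / Beta / Bernoulli marginals.
#'
#' @param prior a [PriorSpec].
#' @param nFeatures number of non-intercept coefficients (ungrouped
#'   families; grouped families take it from the group structure).
#' @param nSweeps total Gibbs sweeps.
#' @param thin keep every `thin`-th sweep.
#' @param seed optional integer seed.
#' @return list of draw matrices/vectors: `beta`, `delta`, `tau2`, `zeta2`,
#'   `lambda2_1`, `omega`, `sigma2_slab`, `tau2g`, `wg`.
#' @export
priorSimulation <- function(prior, nFeatures = NULL, nSweeps = 1e4, thin = 1L,
                            seed = NULL) {
  stopifnot(is(prior, "PriorSpec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(prior@groups)) {
    if (is.null(nFeatures)) stop("nFeatures required for ungrouped families")
    gi <- list(group = rep(0L, nFeatures), gsize = integer(0))
    m <- as.integer(nFeatures)
  } else {
    fn <- featureNames(prior@groups)
    gi <- .groupIndices(prior@groups, fn)
    m <- length(fn)
  }
  if (m < 1L) stop("need at least one feature")
  .cpp_prior_chain(.familyCode(prior@family), m, gi$group, gi$gsize,
    prior@hyper, as.integer(nSweeps), as.integer(thin))
}

setMethod("show", "PriorSpec", function(object) {
  cat(sprintf("PriorSpec: family '%s'%s\n", object@family,
    if (!is.null(object@groups)) {
      sprintf(" with %d groups", nlevels(object@groups@assignment))
    } else ""))
})
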