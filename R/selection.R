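#' @include fit.R
NULL

# the nominal-level grid used for ETI zero-exclusion scoring
.etiGrid <- c(seq(0.01, 0.99, by = 0.01), 0.999)

#' Posterior inclusion probabilities
#'
#' Column means of the binary inclusion-indicator draws:
#' `PIP_j = (1/S) sum_s delta_j^(s)`.
#'
#' @param object an [NBFit] from a spike-and-slab family, or a binary draw
#'   matrix (draws in rows).
#' @param ... unused.
#' @return named vector of per-feature probabilities in [0, 1].
#' @rdname pip
#' @export
setMethod("pip", "matrix", function(object, ...) {
  if (!all(object %in% c(0L, 1L))) stop("indicator draws must be binary")
  colMeans(object)
})

#' @rdname pip
#' @export
setMethod("pip", "NBFit", function(object, ...) {
  if (nrow(object@deltaDraws) == 0L)
    stop("no inclusion indicators: family '", object@family,
      "' selects via credible intervals, not PIPs")
  colMeans(object@deltaDraws)
})

# equal-tailed interval of each column at a nominal level
.etiMatrix <- function(draws, level) {
  if (!(level > 0 && level < 1)) stop("level must lie in (0, 1)")
  a <- (1 - level) / 2
  t(apply(draws, 2, quantile, probs = c(a, 1 - a), names = FALSE))
}

#' Equal-tailed credible intervals
#'
#' Per-feature empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2`
#' of the non-intercept coefficient draws.
#'
#' @param object an [NBFit] or a draw matrix (draws in rows).
#' @param level nominal level in (0, 1).
#' @param ... unused.
#' @return two-column matrix (lower, upper), one row per feature.
#' @rdname credibleIntervals
#' @export
setMethod("credibleIntervals", "matrix", function(object, level = 0.95, ...) {
  if (nrow(object) < 100L) stop("need at least 100 draws")
  out <- .etiMatrix(object, level)
  colnames(out) <- c("lower", "upper")
  out
})

#' @rdname credibleIntervals
#' @export
setMethod("credibleIntervals", "NBFit", function(object, level = 0.95, ...) {
  credibleIntervals(object@betaDraws[, -1, drop = FALSE], level = level)
})

#' Maximal zero-excluding ETI level
#'
#' For each feature, the largest nominal level on a fixed grid
#' (0.01, 0.02, ..., 0.99, 0.999) at which the equal-tailed credible
#' interval excludes zero; 0 when even the 1% interval covers zero. This
#' monotone score orders features exactly as interval-width thresholding
#' does and serves as the horseshoe-family ROC score.
#'
#' @param object an [NBFit] or a coefficient draw matrix (draws in rows).
#' @param ... unused.
#' @return named vector of scores in [0, 1].
#' @rdname etiExclusionLevel
#' @export
setMethod("etiExclusionLevel", "matrix", function(object, ...) {
  if (nrow(object) < 100L) stop("need at least 100 draws")
  grid <- .etiGrid
  probs <- sort(unique(c((1 - grid) / 2, 1 - (1 - grid) / 2)))
  qs <- apply(object, 2, quantile, probs = probs, names = FALSE)
  lo <- qs[match((1 - grid) / 2, probs), , drop = FALSE]
  hi <- qs[match(1 - (1 - grid) / 2, probs), , drop = FALSE]
  excl <- lo > 0 | hi < 0 # grid levels x features
  apply(excl, 2, function(e) if (any(e)) max(grid[e]) else 0)
})

#' @rdname etiExclusionLevel
#' @export
setMethod("etiExclusionLevel", "NBFit", function(object, ...) {
  etiExclusionLevel(object@betaDraws[, -1, drop = FALSE])
})

#' ROC curve and AUC
#'
#' AUC is the rank-based Mann-Whitney statistic, counting tied
#' score pairs as half-concordant; it is invariant to strictly increasing
#' transformations of the scores.
#'
#' @param scores per-feature real scores (higher = more evidence).
#' @param truth per-feature logical ground truth, at least one `TRUE` and
#'   one `FALSE`.
#' @return list with `auc` and `curve` (data frame of fpr, tpr, threshold).
#' @export
rocAuc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("scores and truth lengths differ")
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("truth must contain at least one positive and one negative")
  auc <- (sum(rank(scores)[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !truth) / n0, numeric(1))
  curve <- data.frame(
    fpr = c(0, fpr), tpr = c(0, tpr), threshold = c(Inf, thr)
  )
  list(auc = auc, curve = curve)
}

#' Variable selection from a fitted model
#'
#' Spike-and-slab families select features with `PIP >= pipThreshold`
#' (0.5 reproduces the median probability model; applications often use
#' 0.6). Horseshoe-family (and normal-prior) fits select features whose
#' equal-tailed interval at `etiLevel` excludes zero. Supplying the rule
#' that does not match the family is an error.
#'
#' @param object an [NBFit].
#' @param pipThreshold PIP cutoff (spike-and-slab families).
#' @param etiLevel credible level (horseshoe families), e.g. 0.95.
#' @param ... unused.
#' @return data frame with one row per non-intercept feature: `feature`,
#'   `group`, `posteriorMean`, `score` (PIP or maximal zero-excluding ETI
#'   level), `selected`.
#' @export
setMethod("selectFeatures", "NBFit", function(object, pipThreshold = NULL,
                                              etiLevel = NULL, ...) {
  isSS <- object@family %in% c("ss", "grouped_ss")
  if (isSS) {
    if (!is.null(etiLevel))
      stop("family '", object@family, "' selects via PIPs; use pipThreshold")
    if (is.null(pipThreshold)) pipThreshold <- 0.5
    score <- pip(object)
    selected <- score >= pipThreshold
    rule <- sprintf("PIP >= %g", pipThreshold)
  } else {
    if (!is.null(pipThreshold))
      stop("family '", object@family,
        "' has no inclusion indicators; use etiLevel")
    if (is.null(etiLevel)) etiLevel <- 0.95
    ci <- credibleIntervals(object, level = etiLevel)
    selected <- ci[, 1] > 0 | ci[, 2] < 0
    score <- etiExclusionLevel(object)
    rule <- sprintf("%g%% ETI excludes zero", 100 * etiLevel)
  }
  grp <- object@config$groups
  out <- data.frame(
    feature = object@featureNames,
    group = if (!is.null(grp)) unname(grp[object@featureNames]) else NA_character_,
    posteriorMean = unname(colMeans(object@betaDraws[, -1, drop = FALSE])),
    score = unname(score),
    selected = unname(selected),
    row.names = NULL
  )
  attr(out, "rule") <- rule
  out
})
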