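#' @include AllGenerics.R
NULL

#' Construct a spatially indexed count dataset
#'
#' @param counts nonnegative integer outcome vector.
#' @param features numeric matrix or data frame of non-intercept features;
#'   the intercept column is added internally and must not be supplied.
#' @param offset optional additive offset on the linear predictor (e.g.
#'   [rateOffset()] output for rate models); default zero.
#' @param labels optional location labels; defaults to `loc1, loc2, ...`.
#' @return a [CountData] object.
#' @examples
#' d <- countData(rpois(5, 2), matrix(rnorm(10), 5, 2))
#' nLocations(d)
#' @export
countData <- function(counts, features, offset = NULL, labels = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("features must be numeric")
  n <- length(counts)
  if (nrow(features) != n) stop("features row count must match counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(apply(features, 2, function(x) all(x == 1))))
    stop("features must not contain an intercept column; it is added internally")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  design <- cbind("(Intercept)" = 1, features)
  if (is.null(offset)) offset <- rep(0, n)
  if (length(offset) == 1L) offset <- rep(offset, n)
  if (is.null(labels)) labels <- paste0("loc", seq_len(n))
  new("CountData",
    counts = as.integer(counts), design = design,
    offset = as.numeric(offset), labels = as.character(labels)
  )
}

#' Read a count dataset from a CSV file
#'
#' The file must contain one designated outcome column; an optional offset
#' column and an optional location-label column may be named. All remaining
#' columns become features (the intercept is never read from file).
#'
#' @param path CSV path with a header row.
#' @param outcome name of the count column.
#' @param offset optional name of the offset column.
#' @param labels optional name of the location-label column.
#' @return a [CountData].
#' @export
readCountData <- function(path, outcome, offset = NULL, labels = NULL) {
  tab <- read.csv(path, check.names = FALSE)
  for (col in c(outcome, offset, labels)) {
    if (!col %in% names(tab)) stop("column not found in ", path, ": ", col)
  }
  y <- tab[[outcome]]
  off <- if (!is.null(offset)) tab[[offset]] else NULL
  labs <- if (!is.null(labels)) as.character(tab[[labels]]) else NULL
  feat <- tab[setdiff(names(tab), c(outcome, offset, labels))]
  countData(y, as.matrix(feat), offset = off, labels = labs)
}

#' Offset for rate-scale modelling
#'
#' For counts interpreted as rates per `per` population units, the linear
#' predictor carries `log(population) - log(per)`.
#'
#' @param population positive per-location population counts.
#' @param per rate base (default 100000).
#' @export
rateOffset <- function(population, per = 1e5) {
  if (any(population <= 0)) stop("population counts must be positive")
  log(population) - log(per)
}

#' Linear predictor of the NB model
#'
#' `eta = K beta + phi + offset`, where K is the design matrix (intercept
#' first). The NB mean is `r * exp(eta)` and the logit-scale probability is
#' `psi = plogis(eta)`.
#'
#' @param data a [CountData].
#' @param beta coefficient vector of length `ncol(designMatrix(data))`.
#' @param phi spatial field (default zero).
#' @return the linear predictor vector.
#' @export
linearPredictor <- function(data, beta, phi = 0) {
  stopifnot(is(data, "CountData"))
  K <- data@design
  if (length(beta) != ncol(K))
    stop(sprintf("beta has length %d but the design has %d columns",
      length(beta), ncol(K)))
  if (length(phi) == 1L) phi <- rep(phi, nrow(K))
  if (length(phi) != nrow(K)) stop("phi length must match the number of locations")
  drop(K %*% beta) + phi + data@offset
}

#' Log-pmf of the logit-link negative binomial
#'
#' `log NB(y | psi, r)` with `psi = plogis(eta)` and pmf proportional to
#' `psi^y (1 - psi)^r`; the implied mean is `r * exp(eta)`.
#'
#' @param y nonnegative integer count(s).
#' @param eta linear predictor value(s).
#' @param r positive dispersion.
#' @export
nbLogPmf <- function(y, eta, r) {
  if (any(y < 0)) stop("counts must be nonnegative")
  if (r <= 0) stop("dispersion r must be positive")
  dnbinom(y, size = r, prob = plogis(-eta), log = TRUE)
}

#' Draw Polya-Gamma random variates
#'
#' Samples PG(b, c) for real shape `b > 0` via the exact sum-of-gammas series
#' truncated at 40 terms with a moment-matched Gamma tail; the mean
#' `(b / 2c) tanh(c / 2)` is preserved exactly.
#'
#' @param n number of draws.
#' @param b shape parameter(s), positive reals (recycled).
#' @param c tilt parameter(s) (recycled).
#' @export
rPolyaGamma <- function(n, b, c = 0) {
  if (any(b <= 0)) stop("b must be positive")
  if (any(!is.finite(c))) stop("c must be finite")
  .cpp_rpg(as.integer(n), as.numeric(b), as.numeric(c))
}

#' Sample Polya-Gamma latents for a dataset
#'
#' One latent `omega_i ~ PG(y_i + r, eta_i)` per observation, plus the
#' pseudo-responses `kappa_i = (y_i - r) / 2`.
#'
#' @param data a [CountData].
#' @param eta current linear predictor.
#' @param r current dispersion.
#' @return list with elements `omega` and `kappa`.
#' @export
samplePGLatents <- function(data, eta, r) {
  stopifnot(is(data, "CountData"))
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  y <- data@counts
  list(
    omega = .cpp_rpg(length(y), y + r, eta),
    kappa = (y - r) / 2
  )
}

#' Joint Gaussian update of regression coefficients
#'
#' Draws the included coordinates jointly from the Gaussian full conditional
#' with precision `K' Omega K + V^{-1}` and mean solving that precision
#' against `K'(kappa - Omega (phi + offset))`; excluded coordinates are set
#' to exact zero. The intercept (first coordinate) is always included.
#'
#' @param data a [CountData].
#' @param omega Polya-Gamma latents.
#' @param kappa pseudo-responses `(y - r) / 2`.
#' @param phi spatial field (default zero).
#' @param priorVar length-p vector of prior variances (intercept first).
#' @param include logical length-p inclusion mask; `include[1]` must be TRUE.
#' @return a coefficient draw of length p.
#' @export
sampleCoefficients <- function(data, omega, kappa, phi = 0, priorVar,
                               include = NULL) {
  stopifnot(is(data, "CountData"))
  K <- data@design
  p <- ncol(K)
  if (is.null(include)) include <- rep(TRUE, p)
  if (!include[1]) stop("the intercept is always included")
  if (length(priorVar) != p) stop("priorVar must have one entry per design column")
  if (any(priorVar[include] <= 0)) stop("prior variances of included coordinates must be positive")
  if (length(phi) == 1L) phi <- rep(phi, nrow(K))
  drop(.cpp_sample_beta(K, omega, kappa, phi + data@offset, priorVar,
    as.integer(include)))
}

#' Chinese-restaurant-table draws
#'
#' `l ~ CRT(y, r)`, the number of occupied tables after `y` seatings with
#' concentration `r`; used in the conjugate dispersion update.
#'
#' @param y nonnegative integer count(s).
#' @param r positive concentration.
#' @export
rCRT <- function(y, r) {
  if (r <= 0) stop("r must be positive")
  .cpp_crt(as.integer(y), r)
}

#' Gibbs update of the NB dispersion
#'
#' CRT-Gamma augmentation: latent table counts `l_i ~ CRT(y_i, r)` then
#' `r ~ Gamma(a_r + sum l_i, b_r + sum log(1 + exp(eta_i)))` (shape-rate).
#'
#' @param data a [CountData].
#' @param eta current linear predictor.
#' @param r current dispersion (the CRT concentration).
#' @param aR,bR Gamma hyperparameters (default 1, 1).
#' @return one positive draw.
#' @export
sampleDispersion <- function(data, eta, r, aR = 1, bR = 1) {
  stopifnot(is(data, "CountData"))
  l <- sum(.cpp_crt(data@counts, r))
  rate <- bR + sum(ifelse(eta > 30, eta, log1p(exp(eta))))
  rgamma(1L, shape = aR + l, rate = rate)
}

#' @describeIn CountData-class outcome counts
#' @param object a `CountData`
#' @export
setMethod("counts", "CountData", function(object, ...)
  setNames(object@counts, object@labels))

#' @describeIn CountData-class design matrix including the intercept column
#' @export
setMethod("designMatrix", "CountData", function(object, ...) object@design)

#' @describeIn CountData-class linear-predictor offsets
#' @export
setMethod("offsets", "CountData", function(object, ...) object@offset)

#' @describeIn CountData-class location labels
#' @export
setMethod("locationLabels", "CountData", function(object, ...) object@labels)

#' @describeIn CountData-class number of locations
#' @export
setMethod("nLocations", "CountData", function(object, ...) length(object@counts))

#' @describeIn CountData-class non-intercept feature names
#' @export
setMethod("featureNames", "CountData", function(object, ...)
  colnames(object@design)[-1])

setMethod("show", "CountData", function(object) {
  cat(sprintf(
    "CountData: %d locations, %d features (+ intercept); counts %d-%d%s\n",
    length(object@counts), ncol(object@design) - 1L,
    min(object@counts), max(object@counts),
    if (any(object@offset != 0)) ", with offset" else ""
  ))
})
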