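#' @include graph.R nbcore.R priors.R
NULL

#' AR(1)-correlated Gaussian features
#'
#' Rows are iid `N(0, scale * Sigma)` with `Sigma[j, k] = rho^|j - k|`.
#'
#' @param n number of rows (locations).
#' @param m number of features.
#' @param rho AR(1) correlation, `|rho| < 1`.
#' @param scale overall covariance scale (default 0.1).
#' @export
arFeatures <- function(n, m, rho, scale = 0.1) {
  if (abs(rho) >= 1) stop("|rho| must be below 1")
  Sigma <- scale * rho^abs(outer(seq_len(m), seq_len(m), "-"))
  x <- MASS::mvrnorm(n, rep(0, m), Sigma)
  x <- matrix(x, nrow = n)
  colnames(x) <- paste0("x", seq_len(m))
  x
}

#' Block-grouped features with within-group AR(1) correlation
#'
#' Distinct groups are mutually independent; within a group the columns
#' follow an AR(1) correlation at `rho`, overall scale `scale`.
#'
#' @param n number of rows.
#' @param sizes integer vector of group sizes.
#' @param rho within-group AR(1) correlation.
#' @param scale overall covariance scale (default 0.1).
#' @return list with `features` (matrix) and `groups` (a [GroupStructure]).
#' @export
groupedFeatures <- function(n, sizes, rho, scale = 0.1) {
  if (any(sizes < 1)) stop("group sizes must be positive")
  blocks <- lapply(sizes, function(mg) arFeatures(n, mg, rho, scale))
  x <- do.call(cbind, blocks)
  colnames(x) <- paste0("x", seq_len(ncol(x)))
  assignment <- setNames(
    rep(paste0("g", seq_along(sizes)), times = sizes), colnames(x)
  )
  list(features = x, groups = groupStructure(assignment))
}

#' Equicorrelated Gaussian features
#'
#' All pairwise correlations equal `rho` (exchangeable structure), overall
#' scale `scale`. Feasibility requires `-1/(count - 1) < rho < 1`.
#'
#' @param n number of rows.
#' @param count number of features.
#' @param rho common pairwise correlation.
#' @param scale overall covariance scale (default 0.1).
#' @export
equicorrFeatures <- function(n, count, rho, scale = 0.1) {
  if (count > 1 && (rho <= -1 / (count - 1) || rho >= 1))
    stop(sprintf("rho must lie in (%.4f, 1) for %d exchangeable features",
      -1 / (count - 1), count))
  Sigma <- scale * ((1 - rho) * diag(count) + rho)
  x <- MASS::mvrnorm(n, rep(0, count), Sigma)
  x <- matrix(x, nrow = n)
  colnames(x) <- paste0("s", seq_len(count))
  x
}

# group sizes used by the grouped designs: size 5 throughout, with one
# smaller remainder group when 5 does not divide m
.presetGroupSizes <- function(m, size = 5L) {
  sizes <- rep(size, m %/% size)
  if (m %% size > 0L) sizes <- c(sizes, m %% size)
  sizes
}

#' Simulate a spatial count study with known ground truth
#'
#' Three lattice-based designs, all with exactly ten non-null coefficients
#' and NB outcomes at dispersion `r`:
#' \describe{
#'   \item{sim1}{no group structure: AR(1)-correlated features at `rho`,
#'     ten random signals of size `effect` (default 2), and an ICAR spatial
#'     field at precision `nu * Q + 1e-8 * I` on a queen-contiguity grid
#'     (10 x 5 for n = 50, 10 x 10 for n = 100).}
#'   \item{sim2}{features in independent AR(1) blocks of five (one smaller
#'     remainder block); signals drawn `Unif(0.5, 2)` and placed either in
#'     two fully active size-five groups (`case = "full"`) or in three
#'     partially active groups with 4/3/3 active members
#'     (`case = "partial"`); no spatial field.}
#'   \item{sim3}{first `p/2` features in AR(1) blocks of five, the remaining
#'     `p/2 - 1` as equicorrelated singletons (pairwise `rho`); ten signals
#'     of size `effect` (default 4) split evenly: five in the grouped half
#'     (one full group, or 3 + 2 across two groups for `case = "partial"`)
#'     and five among the singletons; ICAR field as in sim1.}
#' }
#' Feature generation, signal placement, the spatial field, and the outcome
#' draw each consume a dedicated seed stream derived from `seed`, so the
#' same seed regenerates the study bit-identically.
#'
#' @param design `"sim1"`, `"sim2"`, or `"sim3"`.
#' @param n sample size, 50 or 100 (fixing the lattice).
#' @param p total number of coefficients including the intercept.
#' @param rho feature correlation (AR(1) within blocks; pairwise among
#'   sim3 singletons). Default 0.5.
#' @param nu ICAR precision multiplier (sim1/sim3); must be `NULL` for sim2,
#'   which has no spatial effect.
#' @param case signal configuration for sim2/sim3: `"full"` or `"partial"`.
#' @param effect non-null coefficient size; default 2 (sim1), 4 (sim3);
#'   sim2 always draws `Unif(0.5, 2)`.
#' @param r NB dispersion of the generated outcomes (default 1).
#' @param seed integer seed.
#' @return a [SimulatedStudy].
#' @export
simulateScenario <- function(design = c("sim1", "sim2", "sim3"), n = 100,
                             p = 50, rho = 0.5, nu = NULL,
                             case = c("full", "partial"), effect = NULL,
                             r = 1, seed = NULL) {
  design <- match.arg(design)
  case <- match.arg(case)
  if (!n %in% c(50L, 100L))
    stop("presets place locations on a 10 x 5 (n = 50) or 10 x 10 (n = 100) grid")
  m <- p - 1L
  if (m < 10L) stop("presets carry ten non-null coefficients; need p >= 11")
  if (design == "sim2") {
    if (!is.null(nu)) stop("sim2 has no spatial random effect; nu must be NULL")
  } else {
    if (is.null(nu)) nu <- 0.25
    if (nu <= 0) stop("nu must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  streams <- sample.int(.Machine$integer.max - 1L, 4L)
  nSignals <- 10L

  grid <- if (design == "sim2") NULL else if (n == 50L) {
    queenGrid(10, 5)
  } else {
    queenGrid(10, 10)
  }

  set.seed(streams[1]) # features
  groups <- NULL
  if (design == "sim1") {
    X <- arFeatures(n, m, rho)
  } else if (design == "sim2") {
    sizes <- .presetGroupSizes(m)
    gf <- groupedFeatures(n, sizes, rho)
    X <- gf$features
    groups <- gf$groups
  } else {
    if (p %% 2L != 0L || (p / 2) %% 5L != 0L)
      stop("sim3 needs p divisible by 10 so the grouped half splits into fives")
    nGrouped <- p / 2
    nSingle <- p / 2 - 1L
    gf <- groupedFeatures(n, rep(5L, nGrouped / 5L), rho)
    Xs <- equicorrFeatures(n, nSingle, rho)
    X <- cbind(gf$features, Xs)
    colnames(X) <- paste0("x", seq_len(m))
    assignment <- c(
      setNames(groupOf(gf$groups), colnames(X)[seq_len(nGrouped)]),
      setNames(paste0("s", seq_len(nSingle)), colnames(X)[nGrouped + seq_len(nSingle)])
    )
    groups <- groupStructure(assignment)
  }

  set.seed(streams[2]) # signal placement and magnitudes
  beta <- rep(0, p)
  support <- rep(FALSE, m)
  if (design == "sim1") {
    if (is.null(effect)) effect <- 2
    idx <- sample.int(m, nSignals)
    support[idx] <- TRUE
    beta[idx + 1L] <- effect
  } else if (design == "sim2") {
    sizes <- as.vector(groupSizes(groups))
    glab <- groupOf(groups)
    gnames <- names(groupSizes(groups))
    if (case == "full") {
      eligible <- gnames[sizes == 5L]
      picked <- sample(eligible, 2L)
      idx <- which(glab %in% picked)
    } else {
      picked <- sample(gnames[sizes >= 4L], 3L)
      counts <- c(4L, 3L, 3L)
      idx <- unlist(lapply(seq_along(picked), function(i) {
        members <- which(glab == picked[i])
        sample(members, counts[i])
      }))
    }
    support[idx] <- TRUE
    beta[idx + 1L] <- runif(nSignals, 0.5, 2)
  } else {
    if (is.null(effect)) effect <- 4
    glab <- groupOf(groups)
    nGrouped <- p / 2
    groupedGroups <- unique(glab[seq_len(nGrouped)])
    if (case == "full") {
      g <- sample(groupedGroups, 1L)
      idxG <- which(glab == g)
    } else {
      gs <- sample(groupedGroups, 2L)
      idxG <- c(
        sample(which(glab == gs[1]), 3L),
        sample(which(glab == gs[2]), 2L)
      )
    }
    idxS <- nGrouped + sample.int(m - nGrouped, 5L)
    idx <- c(idxG, idxS)
    support[idx] <- TRUE
    beta[idx + 1L] <- effect
  }

  set.seed(streams[3]) # spatial field
  phi <- rep(0, n)
  if (!is.null(grid)) {
    phi <- rICARField(icarPrecision(grid), nu)
  }

  set.seed(streams[4]) # outcomes
  eta <- drop(cbind(1, X) %*% beta) + phi
  y <- rnbinom(n, size = r, prob = plogis(-eta))

  labels <- if (is.null(grid)) paste0("loc", seq_len(n)) else grid@labels
  data <- countData(y, X, labels = labels)
  new("SimulatedStudy",
    data = data, graph = grid, truthBeta = beta, truthSupport = support,
    truthPhi = phi, groups = groups,
    config = list(
      design = design, n = n, p = p, rho = rho, nu = if (design == "sim2") NULL else nu,
      case = case, effect = effect, r = r, seed = seed,
      streams = list(
        features = streams[1], signal = streams[2],
        spatial = streams[3], outcome = streams[4]
      )
    )
  )
}

#' SimulatedStudy accessors
#'
#' @param study a [SimulatedStudy].
#' @name study-accessors
NULL

#' @rdname study-accessors
#' @export
studyData <- function(study) study@data

#' @rdname study-accessors
#' @export
studyGraph <- function(study) study@graph

#' @rdname study-accessors
#' @export
studyGroups <- function(study) study@groups

#' @rdname study-accessors
#' @export
truthBeta <- function(study) study@truthBeta

#' @rdname study-accessors
#' @export
truthSupport <- function(study) {
  setNames(study@truthSupport, featureNames(study@data))
}

#' @rdname study-accessors
#' @export
truthPhi <- function(study) study@truthPhi

setMethod("show", "SimulatedStudy", function(object) {
  cat(sprintf(
    "SimulatedStudy '%s': n = %d, p = %d, %d true signals%s%s\n",
    object@config$design, nLocations(object@data),
    ncol(object@data@design), sum(object@truthSupport),
    if (!is.null(object@graph)) ", with spatial field" else "",
    if (!is.null(object@groups)) {
      sprintf(", %d feature groups", nGroups(object@groups))
    } else ""
  ))
})
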