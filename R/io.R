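#' @include simulate.R selection.R diagnostics.R
NULL

#' Log-transform and standardize a feature table
#'
#' Optional elementwise log (requiring strictly positive entries) followed
#' by optional per-column centring and scaling to unit variance.
#'
#' @param x numeric matrix or data frame of features.
#' @param logTransform take logs first (default FALSE).
#' @param standardize centre and scale each column (default TRUE).
#' @return a numeric matrix.
#' @export
preprocessFeatures <- function(x, logTransform = FALSE, standardize = TRUE) {
  x <- as.matrix(x)
  if (logTransform) {
    bad <- which(apply(x, 2, function(col) any(col <= 0)))
    if (length(bad) > 0L)
      stop("log transform needs strictly positive entries; offending column(s): ",
        paste(colnames(x)[bad], collapse = ", "))
    x <- log(x)
  }
  if (standardize) {
    sds <- apply(x, 2, sd)
    if (any(sds == 0))
      stop("constant column(s) cannot be standardized: ",
        paste(colnames(x)[sds == 0], collapse = ", "))
    x <- scale(x)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  }
  x
}

# run manifest shared by the writers
.manifest <- function(dir, kind, config, extra = list()) {
  files <- setdiff(list.files(dir), "manifest.json")
  digests <- as.list(tools::md5sum(file.path(dir, files)))
  names(digests) <- files
  c(list(
    kind = kind,
    package = "spanbvs",
    version = as.character(utils::packageVersion("spanbvs")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    files = digests
  ), extra)
}

#' Write a simulated study to disk
#'
#' Writes `features.csv` (with a `location` label column), `outcome.csv`,
#' `adjacency.tsv` (edge list; omitted for aspatial designs), `groups.tsv`
#' (omitted without groups), `truth.json`, and `manifest.json`. Identical
#' studies write byte-identical data files.
#'
#' @param study a [SimulatedStudy].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "SimulatedStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- study@data
  feat <- data.frame(location = d@labels, d@design[, -1, drop = FALSE],
    check.names = FALSE)
  write.csv(feat, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(data.frame(location = d@labels, count = d@counts),
    file.path(dir, "outcome.csv"), row.names = FALSE)
  if (!is.null(study@graph)) {
    e <- study@graph@edges
    edges <- data.frame(
      from = study@graph@labels[e[, 1]],
      to = study@graph@labels[e[, 2]]
    )
    write.table(edges, file.path(dir, "adjacency.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(study@groups)) {
    g <- groupOf(study@groups)
    write.table(data.frame(feature = names(g), group = unname(g)),
      file.path(dir, "groups.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  truth <- list(
    beta = study@truthBeta,
    support = study@truthSupport,
    phi = study@truthPhi,
    config = study@config
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(.manifest(dir, "study", study@config),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a study bundle written by [writeStudy()]
#'
#' @param dir the bundle directory.
#' @return list with `data` ([CountData]), `graph` (or NULL), `groups`
#'   (or NULL), and `truth` (list, or NULL when no truth.json is present).
#' @export
readStudy <- function(dir) {
  # outcome lives in its own file; join on the location label, never row order
  out <- read.csv(file.path(dir, "outcome.csv"))
  feat <- read.csv(file.path(dir, "features.csv"), check.names = FALSE)
  if (!setequal(out$location, feat$location))
    stop("outcome and feature files cover different locations")
  out <- out[match(feat$location, out$location), ]
  data <- countData(out$count,
    as.matrix(feat[setdiff(names(feat), "location")]),
    labels = as.character(feat$location))
  graph <- NULL
  adjPath <- file.path(dir, "adjacency.tsv")
  if (file.exists(adjPath)) graph <- readAdjacency(adjPath, labels = data@labels)
  groups <- NULL
  grpPath <- file.path(dir, "groups.tsv")
  if (file.exists(grpPath)) groups <- readGroups(grpPath, featureNames(data))
  truth <- NULL
  truthPath <- file.path(dir, "truth.json")
  if (file.exists(truthPath)) truth <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
  list(data = data, graph = graph, groups = groups, truth = truth)
}

#' Export a fitted model to disk
#'
#' Writes one CSV per stored parameter block (`beta.csv`, `delta.csv`,
#' `phi.csv`, `traces.csv`, group traces), the selection report
#' (`selection.csv`), the Geweke table (`geweke.csv`), and a JSON run
#' manifest recording the seed, configuration, invariant checks, and
#' convergence summary.
#'
#' @param fit an [NBFit].
#' @param dir output directory (created if needed).
#' @param pipThreshold,etiLevel selection rule forwarded to
#'   [selectFeatures()]; defaults by family.
#' @return `dir`, invisibly.
#' @export
writeFit <- function(fit, dir, pipThreshold = NULL, etiLevel = NULL) {
  stopifnot(is(fit, "NBFit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(fit@betaDraws, file.path(dir, "beta.csv"), row.names = FALSE)
  if (nrow(fit@deltaDraws) > 0)
    write.csv(fit@deltaDraws, file.path(dir, "delta.csv"), row.names = FALSE)
  if (nrow(fit@phiDraws) > 0)
    write.csv(fit@phiDraws, file.path(dir, "phi.csv"), row.names = FALSE)
  write.csv(fit@traces, file.path(dir, "traces.csv"), row.names = FALSE)
  for (nm in names(fit@groupTraces)) {
    write.csv(fit@groupTraces[[nm]], file.path(dir, paste0(nm, ".csv")),
      row.names = FALSE)
  }
  sel <- selectFeatures(fit, pipThreshold = pipThreshold, etiLevel = etiLevel)
  write.csv(sel, file.path(dir, "selection.csv"), row.names = FALSE)
  diag <- diagnosticsReport(fit)
  write.csv(diag$geweke, file.path(dir, "geweke.csv"), row.names = FALSE)
  invariants <- list(
    phi_sum_zero = nrow(fit@phiDraws) == 0 ||
      max(abs(rowSums(fit@phiDraws))) < 1e-8,
    r_positive = all(fit@traces$r > 0),
    delta_binary = nrow(fit@deltaDraws) == 0 ||
      all(fit@deltaDraws %in% c(0L, 1L))
  )
  manifest <- .manifest(dir, "fit", fit@config, extra = list(
    invariants = invariants,
    geweke = list(
      fractionPassing = diag$fractionPassing,
      retained = diag$retained
    ),
    selectionRule = attr(sel, "rule")
  ))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Score a fit against known truth
#'
#' Uses posterior inclusion probabilities for spike-and-slab families and
#' maximal zero-excluding ETI levels for horseshoe families as ROC scores.
#'
#' @param fit an [NBFit].
#' @param truth logical ground-truth support over the non-intercept
#'   features, or a [SimulatedStudy].
#' @return list with `scores`, `auc`, and `curve`.
#' @export
evaluateSelection <- function(fit, truth) {
  stopifnot(is(fit, "NBFit"))
  if (is(truth, "SimulatedStudy")) truth <- truthSupport(truth)
  if (length(truth) != length(fit@featureNames))
    stop("truth does not match the fitted features")
  if (!is.null(names(truth)) &&
    !identical(names(truth), fit@featureNames))
    stop("truth feature names do not match the fit")
  scores <- if (fit@family %in% c("ss", "grouped_ss")) {
    pip(fit)
  } else {
    etiExclusionLevel(fit)
  }
  r <- rocAuc(scores, truth)
  list(scores = scores, auc = r$auc, curve = r$curve)
}
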