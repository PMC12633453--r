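#' @include AllGenerics.R
NULL

# internal: assemble a SpatialGraph from an integer edge matrix
.newGraph <- function(edges, labels) {
  n <- length(labels)
  dimnames(edges) <- NULL
  if (nrow(edges) > 0L) {
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  storage.mode(edges) <- "integer"
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  if (nrow(edges) > 0L) {
    ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
    memb <- as.integer(igraph::components(ig)$membership)
  } else {
    memb <- seq_len(n)
  }
  new("SpatialGraph",
    nNodes = as.integer(n), edges = edges, labels = labels,
    degrees = as.integer(deg), membership = memb
  )
}

#' Queen-contiguity graph on a rectangular lattice
#'
#' Builds the neighbourhood graph of an `nRows` x `nCols` grid under queen
#' contiguity: cells sharing an edge or a corner are neighbours. Interior
#' cells have degree 8, non-corner border cells 5, corner cells 3.
#'
#' @param nRows,nCols lattice dimensions; the product must be at least 2.
#' @return a [SpatialGraph] with nodes labelled `"r<i>c<j>"` in row-major order.
#' @examples
#' g <- queenGrid(10, 5)
#' table(degrees(g))
#' @export
queenGrid <- function(nRows, nCols) {
  nRows <- as.integer(nRows)
  nCols <- as.integer(nCols)
  if (nRows < 1L || nCols < 1L) stop("grid dimensions must be positive")
  if (nRows * nCols < 2L) stop("a single-cell grid has no valid ICAR graph")
  idx <- function(i, j) (i - 1L) * nCols + j
  from <- integer(0)
  to <- integer(0)
  for (i in seq_len(nRows)) {
    for (j in seq_len(nCols)) {
      # connect to E, S, SE, SW so each unordered pair appears once
      if (j < nCols) { from <- c(from, idx(i, j)); to <- c(to, idx(i, j + 1L)) }
      if (i < nRows) { from <- c(from, idx(i, j)); to <- c(to, idx(i + 1L, j)) }
      if (i < nRows && j < nCols) { from <- c(from, idx(i, j)); to <- c(to, idx(i + 1L, j + 1L)) }
      if (i < nRows && j > 1L) { from <- c(from, idx(i, j)); to <- c(to, idx(i + 1L, j - 1L)) }
    }
  }
  labels <- as.vector(t(outer(seq_len(nRows), seq_len(nCols),
    function(i, j) sprintf("r%dc%d", i, j))))
  .newGraph(cbind(from, to), labels)
}

#' Graph from a list of labelled node pairs
#'
#' Duplicate and reversed pairs collapse to a single undirected edge.
#'
#' @param pairs two-column matrix or data frame of node labels, one edge per row.
#' @param labels ordered vector of all node labels.
#' @return a [SpatialGraph].
#' @export
graphFromEdges <- function(pairs, labels) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("node labels must be unique")
  a <- match(as.character(pairs[, 1]), labels)
  b <- match(as.character(pairs[, 2]), labels)
  if (anyNA(a) || anyNA(b)) {
    bad <- unique(c(pairs[, 1][is.na(a)], pairs[, 2][is.na(b)]))
    stop("unknown node label(s): ", paste(bad, collapse = ", "))
  }
  if (any(a == b)) stop("self-pairs are not allowed")
  .newGraph(cbind(a, b), labels)
}

#' Read a spatial adjacency specification from disk
#'
#' Two formats are supported: a TSV edge list with two label columns
#' (header optional), or a dense labelled 0/1 CSV matrix, which must be
#' symmetric with a zero diagonal.
#'
#' @param path file path.
#' @param labels ordered node labels; required for edge lists, checked
#'   against row/column names for matrices (optional there).
#' @param format `"edgelist"`, `"matrix"`, or `"auto"` (by file extension:
#'   `.tsv` edge list, `.csv` matrix).
#' @return a [SpatialGraph].
#' @export
readAdjacency <- function(path, labels = NULL, format = c("auto", "edgelist", "matrix")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "matrix" else "edgelist"
  }
  if (format == "edgelist") {
    if (is.null(labels)) stop("an edge list needs an ordered `labels` vector")
    raw <- read.delim(path, header = FALSE, colClasses = "character")
    if (ncol(raw) != 2L) stop("edge list must have exactly two columns")
    # header optional: drop the first row when it does not name known nodes
    if (nrow(raw) > 0L && !(raw[1, 1] %in% labels) && !(raw[1, 2] %in% labels)) {
      raw <- raw[-1, , drop = FALSE]
    }
    graphFromEdges(raw, labels)
  } else {
    m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
    if (nrow(m) != ncol(m)) stop("adjacency matrix must be square")
    if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
      stop("adjacency matrix must be symmetric")
    if (!all(m %in% c(0, 1))) stop("adjacency matrix entries must be 0 or 1")
    if (any(diag(m) != 0)) stop("adjacency matrix must have a zero diagonal")
    labs <- if (is.null(labels)) colnames(m) else as.character(labels)
    if (!identical(colnames(m), labs)) {
      if (!setequal(colnames(m), labs)) stop("matrix labels do not match `labels`")
      m <- m[labs, labs]
    }
    e <- which(upper.tri(m) & m == 1, arr.ind = TRUE)
    .newGraph(e, labs)
  }
}

#' ICAR precision structure for a graph
#'
#' Computes Q = D - W, where W is the graph adjacency matrix and D the
#' diagonal matrix of neighbour counts. Q is rank deficient by the number of
#' connected components; adding `nugget` to the diagonal makes it positive
#' definite.
#'
#' @param graph a [SpatialGraph].
#' @param nugget small positive diagonal precision (default `1e-8`).
#' @return an [ICARPrior].
#' @export
icarPrecision <- function(graph, nugget = 1e-8) {
  stopifnot(is(graph, "SpatialGraph"))
  if (nugget <= 0) stop("nugget must be positive")
  n <- graph@nNodes
  Q <- matrix(0, n, n, dimnames = list(graph@labels, graph@labels))
  e <- graph@edges
  Q[e] <- -1
  Q[e[, 2:1, drop = FALSE]] <- -1
  diag(Q) <- graph@degrees
  new("ICARPrior",
    Q = Q, nugget = nugget,
    rankDeficiency = max(graph@membership),
    membership = graph@membership, labels = graph@labels
  )
}

#' Draw zero-centred ICAR fields
#'
#' Samples from the zero-mean Gaussian with precision `nu * Q + nugget * I`
#' and recentres each draw to sum exactly to zero within every graph
#' component (the sum-to-zero constraint that identifies the field against
#' the intercept).
#'
#' @param prior an [ICARPrior].
#' @param nu positive precision multiplier; smaller values yield
#'   larger-amplitude (more strongly spatially structured) fields.
#' @param nDraws number of fields to draw.
#' @return a numeric vector if `nDraws = 1`, else an `nDraws` x n matrix.
#' @export
rICARField <- function(prior, nu, nDraws = 1L) {
  stopifnot(is(prior, "ICARPrior"))
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0) stop("nu must be a positive scalar")
  n <- nrow(prior@Q)
  P <- nu * prior@Q
  diag(P) <- diag(P) + prior@nugget
  R <- chol(P)
  z <- matrix(rnorm(n * nDraws), n, nDraws)
  x <- backsolve(R, z) # rows: locations
  memb <- prior@membership
  for (cmp in seq_len(max(memb))) {
    sel <- memb == cmp
    x[sel, ] <- sweep(x[sel, , drop = FALSE], 2, colMeans(x[sel, , drop = FALSE]))
  }
  if (nDraws == 1L) x[, 1] else t(x)
}

#' Gibbs update of the spatial field
#'
#' Draws the ICAR field from its Gaussian full conditional with precision
#' `nu * Q + nugget * I + diag(omega)` and mean solving that precision
#' against `kappa - omega * cvec`, where `omega` are the Polya-Gamma
#' latents, `kappa = (y - r) / 2`, and `cvec` is the non-spatial part of the
#' linear predictor. The draw is recentred to sum to zero per component.
#'
#' @param prior an [ICARPrior].
#' @param nu positive precision multiplier.
#' @param omega positive Polya-Gamma latents.
#' @param kappa vector `(y - r) / 2`.
#' @param cvec non-spatial linear predictor (design effects plus offset).
#' @return the updated spatial field.
#' @export
samplePhi <- function(prior, nu, omega, kappa, cvec) {
  stopifnot(is(prior, "ICARPrior"))
  if (any(!is.finite(cvec)))
    stop("non-finite linear predictor passed to the spatial update")
  if (any(omega <= 0)) stop("Polya-Gamma latents must be positive")
  drop(.cpp_sample_phi(prior@Q, prior@nugget, nu, omega, kappa, cvec,
    as.integer(prior@membership - 1L)))
}

#' Gibbs update of the ICAR precision multiplier
#'
#' Conjugate draw `nu ~ Gamma(a + (n - k) / 2, b + phi' Q phi / 2)`
#' (shape-rate), where k is the number of graph components.
#'
#' @param phi current spatial field (must sum to zero).
#' @param prior an [ICARPrior].
#' @param aNu,bNu Gamma hyperparameters (default 0.1, 0.1).
#' @return one positive draw.
#' @export
sampleNu <- function(phi, prior, aNu = 0.1, bNu = 0.1) {
  stopifnot(is(prior, "ICARPrior"))
  if (abs(sum(phi)) > 1e-8) stop("phi must satisfy the sum-to-zero constraint")
  n <- nrow(prior@Q)
  quad <- drop(crossprod(phi, prior@Q %*% phi))
  rgamma(1L, shape = aNu + (n - prior@rankDeficiency) / 2, rate = bNu + quad / 2)
}

#' @describeIn SpatialGraph-class number of nodes
#' @param object a `SpatialGraph`
#' @aliases nNodes
#' @export
setMethod("nNodes", "SpatialGraph", function(object, ...) object@nNodes)

#' @describeIn SpatialGraph-class per-node neighbour counts
#' @export
setMethod("degrees", "SpatialGraph", function(object, ...)
  setNames(object@degrees, object@labels))

#' @describeIn SpatialGraph-class the deduplicated edge matrix
#' @export
setMethod("graphEdges", "SpatialGraph", function(object, ...) object@edges)

#' @describeIn SpatialGraph-class number of connected components
#' @export
setMethod("nComponents", "SpatialGraph", function(object, ...)
  max(object@membership))

#' @describeIn SpatialGraph-class node labels
#' @export
setMethod("locationLabels", "SpatialGraph", function(object, ...) object@labels)

setMethod("show", "SpatialGraph", function(object) {
  cat(sprintf(
    "SpatialGraph: %d nodes, %d edges, %d component(s); degree range %d-%d\n",
    object@nNodes, nrow(object@edges), max(object@membership),
    min(object@degrees), max(object@degrees)
  ))
})

setMethod("show", "ICARPrior", function(object) {
  cat(sprintf(
    "ICARPrior: %d x %d precision structure, nugget %g, rank deficiency %d\n",
    nrow(object@Q), ncol(object@Q), object@nugget, object@rankDeficiency
  ))
})
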