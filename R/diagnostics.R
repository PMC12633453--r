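#' @include fit.R
NULL

# spectral density of a trace at frequency zero, estimated with a
# Bartlett-windowed autocovariance sum; returned per-draw variance so that
# var(mean) ~ spectralVar0(x) / length(x)
.spectralVar0 <- function(x, maxLag = floor(sqrt(length(x)))) {
  n <- length(x)
  ac <- drop(acf(x, lag.max = maxLag, type = "covariance",
    plot = FALSE, demean = TRUE)$acf)
  w <- 1 - seq_len(maxLag) / (maxLag + 1)
  max(ac[1] + 2 * sum(w * ac[-1]), 0)
}

#' Geweke convergence statistic
#'
#' Compares the mean of the first `firstFraction` of a trace with the mean
#' of the last `lastFraction`, standardised by spectral-density-at-zero
#' standard errors. For a converged, well-mixed chain the statistic is
#' approximately standard normal.
#'
#' @param trace numeric chain of length at least 100.
#' @param firstFraction,lastFraction window fractions (defaults 0.1, 0.5).
#' @return the z statistic.
#' @export
gewekeZ <- function(trace, firstFraction = 0.1, lastFraction = 0.5) {
  n <- length(trace)
  if (n < 100L) stop("trace must have at least 100 values")
  if (firstFraction + lastFraction > 1) stop("window fractions overlap")
  a <- trace[seq_len(floor(firstFraction * n))]
  b <- trace[seq.int(n - floor(lastFraction * n) + 1L, n)]
  va <- .spectralVar0(a) / length(a)
  vb <- .spectralVar0(b) / length(b)
  if (va + vb <= 0) stop("trace has zero variance; Geweke statistic undefined")
  (mean(a) - mean(b)) / sqrt(va + vb)
}

# effective sample size from the same spectral estimate
.essSpectral <- function(x) {
  v0 <- .spectralVar0(x)
  if (v0 <= 0) return(length(x))
  length(x) * var(x) / v0
}

#' Convergence summary of a fitted model
#'
#' One row per monitored parameter (every regression coefficient plus the
#' scalar traces) with its Geweke z statistic; |z| > 2 is flagged.
#'
#' @param object an [NBFit].
#' @param ... unused.
#' @return data frame with columns `parameter`, `z`, `flagged`.
#' @export
setMethod("gewekeTable", "NBFit", function(object, ...) {
  draws <- cbind(object@betaDraws, as.matrix(object@traces))
  if (nrow(draws) == 0L) stop("fit contains no retained draws")
  z <- vapply(seq_len(ncol(draws)), function(j) {
    x <- draws[, j]
    if (var(x) == 0) return(NA_real_)
    gewekeZ(x)
  }, numeric(1))
  data.frame(
    parameter = colnames(draws), z = z,
    flagged = !is.na(z) & abs(z) > 2,
    row.names = NULL
  )
})

#' Trace plots for a fitted model
#'
#' Draws simple trace plots for the requested parameters (default: the
#' scalar traces plus the first few coefficients), optionally to a PNG file.
#'
#' @param fit an [NBFit].
#' @param parameters character vector of parameter names among
#'   `colnames(betaDraws(fit))` and `names(traces(fit))`; default picks up
#'   to nine.
#' @param file optional PNG path; when given, the plot is written there.
#' @return invisibly, the matrix of plotted traces.
#' @export
plotTraces <- function(fit, parameters = NULL, file = NULL) {
  stopifnot(is(fit, "NBFit"))
  draws <- cbind(fit@betaDraws, as.matrix(fit@traces))
  if (is.null(parameters)) {
    parameters <- head(colnames(draws), 9L)
  }
  bad <- setdiff(parameters, colnames(draws))
  if (length(bad) > 0L) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 300 * ceiling(length(parameters) / 3))
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(ceiling(length(parameters) / 3), min(3, length(parameters))),
    mar = c(2.5, 2.5, 2, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  for (p in parameters) {
    graphics::plot(draws[, p], type = "l", xlab = "", ylab = "", main = p)
  }
  invisible(draws[, parameters, drop = FALSE])
}

#' Diagnostics report
#'
#' The Geweke table plus retained-draw count and the fraction of unflagged
#' parameters.
#'
#' @param fit an [NBFit].
#' @return list with `geweke` (data frame), `retained`, `fractionPassing`.
#' @export
diagnosticsReport <- function(fit) {
  stopifnot(is(fit, "NBFit"))
  g <- gewekeTable(fit)
  ok <- !g$flagged
  list(
    geweke = g,
    retained = nrow(fit@betaDraws),
    fractionPassing = mean(ok[!is.na(g$z)])
  )
}
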