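#' PCA sample scores for an expression matrix
#'
#' Principal-component coordinates of the samples of a features x
#' samples matrix (samples are columns, as in the usual genes x samples
#' layout; the matrix is transposed internally). Features are centered
#' by default and not scaled, the usual convention for expression data.
#' A deterministic sign convention (largest-magnitude loading entry per
#' component made non-negative) keeps scores reproducible across runs.
#'
#' @param A features x samples numeric matrix.
#' @param nComponents number of components to return, at most
#'   \code{min(dim(A))}.
#' @param center,scale passed to the underlying PCA; scaling a
#'   zero-variance feature is an error.
#' @return samples x nComponents matrix of scores, with sample names as
#'   row names and columns \code{PC1, PC2, ...}.
#' @examples
#' A <- matrix(rnorm(60), 10, 6)
#' pcaScores(A, 2)
#' @export
pcaScores <- function(A, nComponents, center = TRUE, scale = FALSE) {
  A <- asDataMatrix(A)
  nComponents <- .checkCount(nComponents, min(dim(A)), "nComponents")
  X <- t(A)
  if (scale) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0))
      stop("cannot scale constant feature '",
           colnames(X)[which(sds == 0)[1L]], "'", call. = FALSE)
  }
  fit <- stats::prcomp(X, center = center, scale. = scale)
  keep <- seq_len(min(nComponents, ncol(fit$x)))
  scores <- fit$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    pivot <- which.max(abs(fit$rotation[, keep[j]]))
    if (fit$rotation[pivot, keep[j]] < 0) scores[, j] <- -scores[, j]
  }
  if (ncol(scores) < nComponents) {  # degenerate: fewer PCs than asked
    pad <- matrix(0, nrow(scores), nComponents - ncol(scores))
    scores <- cbind(scores, pad)
  }
  dimnames(scores) <- list(colnames(A), paste0("PC", seq_len(nComponents)))
  scores
}

#' Group-separation statistic
#'
#' Quantifies how well labelled groups of points separate in an
#' embedding (typically the first principal components): for every
#' unordered pair of distinct groups, all cross-group Euclidean
#' distances are computed and summarized by their median; the statistic
#' is the sum of those medians over all group pairs. With fewer than
#' two groups it is 0. The measure is invariant to translation and
#' rotation of the points and scales linearly with the coordinates.
#'
#' @param points s x d matrix of point coordinates (one row per
#'   sample).
#' @param labels length-s group assignment (factor or character).
#' @return Non-negative scalar.
#' @examples
#' pts <- rbind(c(0, 0), c(0, 1), c(3, 0), c(3, 1))
#' separationMeasure(pts, c("a", "a", "b", "b"))  # (3 + sqrt(10)) / 2
#' @export
separationMeasure <- function(points, labels) {
  points <- as.matrix(points)
  if (!nrow(points))
    stop("no points supplied", call. = FALSE)
  if (!is.numeric(points) || !all(is.finite(points)))
    stop("points must be finite numeric coordinates", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(points))
    stop("labels must match the number of points", call. = FALSE)
  if (any(is.na(labels) | labels == ""))
    stop("every point needs a non-empty label", call. = FALSE)
  groups <- unique(labels)
  if (length(groups) < 2L) return(0)
  total <- 0
  for (i in seq_len(length(groups) - 1L)) {
    for (j in seq.int(i + 1L, length(groups))) {
      P <- points[labels == groups[i], , drop = FALSE]
      Q <- points[labels == groups[j], , drop = FALSE]
      # all cross-group pairwise Euclidean distances
      cross <- sqrt(outer(rowSums(P^2), rowSums(Q^2), "+") -
                      2 * P %*% t(Q))
      total <- total + stats::median(pmax(cross, 0))
    }
  }
  total
}

#' Sweep feature-set size and rank for group separation
#'
#' For every combination of rank parameter \code{k} and feature count
#' \code{c}, selects the top-\code{c} features (rows) of \code{A} by
#' leverage score at rank \code{k} using the requested strategy, runs
#' PCA on the reduced matrix, and computes the group-separation
#' statistic of the sample scores. A baseline row using all features is
#' appended, so the gain (or loss) from the reduction can be read off
#' directly.
#'
#' @param A features x samples matrix.
#' @param labels per-sample group labels (length \code{ncol(A)}).
#' @param kValues,cValues grids of rank parameters and feature counts.
#' @param nComponents number of principal components used for the
#'   separation statistic (default 2, the usual biplot view).
#' @param method selection strategy (default \code{"top.scores"}, the
#'   reproducible choice for feature selection).
#' @param seed optional seed for the randomized strategies.
#' @return data.frame with columns \code{k}, \code{c},
#'   \code{separation}, \code{is_baseline}; the baseline row has
#'   \code{k = NA} and \code{c = nrow(A)}.
#' @export
separationSweep <- function(A, labels, kValues, cValues, nComponents = 2,
                            method = "top.scores", seed = NULL) {
  A <- asDataMatrix(A)
  method <- match.arg(method, CUR_METHODS)
  labels <- as.character(labels)
  if (length(labels) != ncol(A))
    stop("labels must have one entry per sample (column)", call. = FALSE)
  kValues <- vapply(kValues, .checkCount, integer(1L), min(dim(A)), "k")
  cValues <- vapply(cValues, .checkCount, integer(1L), nrow(A), "c")
  s <- truncatedSVD(A, min(dim(A)))

  rows <- vector("list", length(kValues) * length(cValues) + 1L)
  i <- 0L
  for (k in kValues) {
    lev <- leverageScores(s, k)
    for (cc in cValues) {
      sel <- .withSeed(seed, .selectAxis(A, lev, method, cc, "rows"))
      red <- A[sel@indices, , drop = FALSE]
      sc <- pcaScores(red, min(nComponents, min(dim(red))))
      i <- i + 1L
      rows[[i]] <- data.frame(k = k, c = cc,
        separation = separationMeasure(sc, labels),
        is_baseline = FALSE)
    }
  }
  base <- pcaScores(A, min(nComponents, min(dim(A))))
  rows[[i + 1L]] <- data.frame(k = NA_integer_, c = nrow(A),
    separation = separationMeasure(base, labels), is_baseline = TRUE)
  do.call(rbind, rows)
}

#' Data for a leverage-score plot
#'
#' Assembles what a leverage plot displays: every score in original
#' feature order, the indices of the \code{topCount} largest scores to
#' highlight, and the uniform level \code{1/n} -- the score every
#' feature would have if all were equally influential.
#'
#' @param lev a \linkS4class{LeverageScores} (or
#'   \linkS4class{CURDecomposition}).
#' @param axis which axis's scores to plot.
#' @param topCount how many top features to highlight.
#' @return A \linkS4class{LeveragePlotData}.
#' @export
leveragePlotData <- function(lev, axis = c("columns", "rows"), topCount) {
  axis <- match.arg(axis)
  if (is(lev, "CURDecomposition")) lev <- lev@leverage
  stopifnot(is(lev, "LeverageScores"))
  s <- leverage(lev, axis)
  topCount <- .checkCount(topCount, length(s), "topCount")
  hi <- topLeverage(lev, topCount, axis)$index
  new("LeveragePlotData", scores = s, highlighted = as.integer(hi),
      uniformLevel = 1 / length(s), axis = axis)
}

#' Plot leverage scores
#'
#' Thin base-graphics rendering of a \linkS4class{LeveragePlotData}:
#' scores as grey bars in feature order, the highlighted top scores
#' dotted in black, and a dashed line at the uniform level.
#'
#' @param x a \linkS4class{LeveragePlotData}.
#' @param ... further arguments passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plotLeverage <- function(x, ...) {
  stopifnot(is(x, "LeveragePlotData"))
  n <- length(x@scores)
  graphics::plot(seq_len(n), x@scores, type = "h", col = "grey",
                 xlab = x@axis, ylab = "normalized leverage score", ...)
  graphics::points(x@highlighted, x@scores[x@highlighted],
                   pch = 16, col = "black")
  graphics::abline(h = x@uniformLevel, lty = 2, col = "red")
  invisible(x)
}
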