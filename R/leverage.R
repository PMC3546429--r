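#' Validate and name a data matrix
#'
#' Coerces input to a dense numeric matrix and enforces the package's
#' input contract: all entries finite, at least one row and column, and
#' unique non-empty dimension names. Missing or blank names are replaced
#' automatically by the 1-based index rendered as a string, matching the
#' behaviour users expect when a delimited file carries no header.
#'
#' @param x numeric matrix (or object coercible to one).
#' @return The validated matrix with complete dimnames.
#' @examples
#' asDataMatrix(matrix(1:6, 2))
#' @export
asDataMatrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("input must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("input matrix must have at least one row and one column",
         call. = FALSE)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite entry at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  dimnames(x) <- list(.autoNames(rownames(x), nrow(x), "row"),
                      .autoNames(colnames(x), ncol(x), "column"))
  x
}

.autoNames <- function(nm, n, what) {
  if (is.null(nm)) nm <- rep("", n)
  blank <- is.na(nm) | nm == ""
  nm[blank] <- as.character(seq_len(n))[blank]
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop(sprintf("duplicated %s name: '%s'", what, dup[1L]), call. = FALSE)
  nm
}

# Run expr with a temporary seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Truncated singular value decomposition
#'
#' Computes the singular triplets of a dense matrix, orders them by
#' non-increasing singular value, and applies a deterministic sign
#' convention: in each right singular vector the entry of largest
#' absolute value is made non-negative (ties resolved at the lowest
#' index), with the paired left vector flipped accordingly. All
#' \code{min(m, n)} triplets are retained so one factorization serves
#' every rank \code{k} at or below the requested one.
#'
#' @param A numeric matrix (passed through [asDataMatrix()]).
#' @param k requested rank, \code{1 <= k <= min(dim(A))}. The result
#'   always carries at least \code{k} triplets.
#' @return A \linkS4class{TruncatedSVD}.
#' @examples
#' truncatedSVD(diag(c(3, 2, 1)), k = 2)
#' @export
truncatedSVD <- function(A, k) {
  A <- asDataMatrix(A)
  p <- min(dim(A))
  k <- .checkCount(k, p, "k")
  s <- svd(A)
  rownames(s$u) <- rownames(A)
  rownames(s$v) <- colnames(A)
  for (j in seq_len(ncol(s$v))) {
    pivot <- which.max(abs(s$v[, j]))
    if (s$v[pivot, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  new("TruncatedSVD", d = s$d, u = s$u, v = s$v, p = p)
}

.checkCount <- function(x, upper, what) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    stop(sprintf("%s must be a positive integer", what), call. = FALSE)
  if (x > upper)
    stop(sprintf("%s = %d exceeds the maximum of %d", what, as.integer(x),
                 as.integer(upper)), call. = FALSE)
  as.integer(x)
}

#' Normalized statistical leverage scores
#'
#' For column \code{j} the score is the squared mass of the \code{j}-th
#' entries across the top \code{k} right singular vectors, divided by
#' \code{k}; row scores use the left singular vectors (equivalent to
#' computing column scores of the transpose, without a second SVD). Up
#' to the \code{1/k} factor these are the diagonal entries of the hat
#' matrix, the projector onto the top-\code{k} singular subspace. Each
#' axis's scores sum to one and lie in \code{[0, 1/k]}.
#'
#' When the matrix is numerically rank-deficient below \code{k} the
#' singular vectors beyond the rank span an arbitrary basis of the null
#' space; a warning is emitted because the scores then depend on that
#' arbitrary choice.
#'
#' @param x a \linkS4class{TruncatedSVD}, or a matrix (factorized
#'   internally).
#' @param k rank parameter, at most the number of available triplets.
#' @return A \linkS4class{LeverageScores}.
#' @examples
#' leverageScores(diag(c(3, 2, 1)), k = 2)
#' @export
leverageScores <- function(x, k) {
  if (is(x, "TruncatedSVD")) {
    s <- x
  } else {
    s <- truncatedSVD(x, k)
  }
  k <- .checkCount(k, s@p, "k")
  if (s@d[k] < 1e-12 * s@d[1L])
    warning("matrix is numerically rank-deficient below k; ",
            "leverage scores beyond the rank depend on an arbitrary ",
            "null-space basis", call. = FALSE)
  colScores <- rowSums(s@v[, seq_len(k), drop = FALSE]^2) / k
  rowScores <- rowSums(s@u[, seq_len(k), drop = FALSE]^2) / k
  names(colScores) <- rownames(s@v)
  names(rowScores) <- rownames(s@u)
  new("LeverageScores", k = k,
      columnScores = colScores, rowScores = rowScores)
}

#' ColumnSelect sampling probabilities
#'
#' Converts leverage scores into the inclusion probabilities of the
#' randomized ColumnSelect sampler: \code{p_j = min(1, c * score_j)}.
#' The sum of the probabilities is the expected number of selections.
#'
#' @param scores numeric vector of leverage scores along one axis.
#' @param c expected number of selections (non-negative).
#' @return Numeric vector of probabilities in \code{[0, 1]}.
#' @examples
#' samplingProbabilities(c(0.5, 0.3, 0.2), c = 2)
#' @export
samplingProbabilities <- function(scores, c) {
  if (length(c) != 1L || !is.finite(c) || c < 0)
    stop("c must be a non-negative number", call. = FALSE)
  if (any(scores < -1e-12))
    stop("leverage scores must be non-negative", call. = FALSE)
  pmin(1, c * scores)
}

#' Default rank from the singular-value spectrum
#'
#' The rank parameter \code{k} controls which structure leverage scores
#' target, and should normally be chosen on domain grounds. When it is
#' not supplied, the package falls back to the smallest \code{k} whose
#' top-\code{k} singular values sum to strictly more than a threshold
#' fraction (default 80%) of the total singular-value sum. Note the rule
#' operates on the singular values themselves, not their squares.
#'
#' @param d non-increasing vector of singular values, at least one of
#'   them strictly positive.
#' @param threshold fraction of the total spectrum mass, default 0.80.
#' @return The smallest qualifying rank, as an integer.
#' @examples
#' defaultRank(c(50, 30, 15, 5))  # cumulative 50, 80, 95 -> k = 3
#' @export
defaultRank <- function(d, threshold = 0.80) {
  if (!length(d) || any(!is.finite(d)) || any(d < 0))
    stop("singular values must be finite and non-negative", call. = FALSE)
  if (any(diff(d) > 1e-12 * max(d[1L], 1)))
    stop("singular values must be non-increasing", call. = FALSE)
  total <- sum(d)
  if (total <= 0)
    stop("all singular values are zero", call. = FALSE)
  if (length(threshold) != 1L || threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)", call. = FALSE)
  which(cumsum(d) > threshold * total)[1L]
}

#' @describeIn leverage Scores stored in a LeverageScores object.
#' @export
setMethod("leverage", "LeverageScores", function(object,
    axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  if (axis == "columns") object@columnScores else object@rowScores
})

#' @describeIn topLeverage Top features of a LeverageScores object.
#' @export
setMethod("topLeverage", "LeverageScores", function(object, count,
    axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  s <- leverage(object, axis)
  count <- .checkCount(count, length(s), "count")
  ord <- order(-s, seq_along(s))[seq_len(count)]
  data.frame(name = names(s)[ord], index = ord, score = unname(s[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
})
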