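#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Truncated singular value decomposition of a data matrix
#'
#' Holds the leading singular triplets of a matrix under a fixed sign
#' convention (in each right singular vector the entry of largest absolute
#' value is non-negative, ties resolved at the lowest index), so that
#' downstream leverage scores and deterministic selections are reproducible
#' bit-for-bit across runs.
#'
#' @slot d numeric vector of singular values, non-increasing, non-negative.
#' @slot u matrix of left singular vectors (columns orthonormal).
#' @slot v matrix of right singular vectors (columns orthonormal).
#' @slot p integer, number of retained triplets.
#'
#' @seealso [truncatedSVD()]
#' @export
setClass("TruncatedSVD",
  representation(d = "numeric", u = "matrix", v = "matrix", p = "integer"))

setValidity("TruncatedSVD", function(object) {
  msg <- character()
  if (object@p < 1L || ncol(object@u) < object@p || ncol(object@v) < object@p)
    msg <- c(msg, "p must be positive and not exceed the stored vectors")
  if (length(object@d) < object@p)
    msg <- c(msg, "fewer singular values than retained triplets")
  if (any(diff(object@d) > 1e-12 * max(object@d[1L], 1)))
    msg <- c(msg, "singular values must be non-increasing")
  if (any(object@d < -1e-12))
    msg <- c(msg, "singular values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Normalized statistical leverage scores at rank k
#'
#' Per-column and per-row leverage scores of a matrix at rank parameter
#' \code{k}: for column \code{j}, the mean over the top \code{k} right
#' singular vectors of the squared \code{j}-th entry; row scores use the
#' left singular vectors. Each axis's scores are a probability vector
#' (they sum to one) and every score lies in \code{[0, 1/k]}. Up to the
#' \code{1/k} scaling these are the diagonal entries of the hat matrix --
#' the orthogonal projector onto the span of the top \code{k} singular
#' vectors -- which is why they inherit the "leverage" name from
#' regression diagnostics.
#'
#' @slot k integer rank parameter.
#' @slot columnScores named numeric vector, one score per column.
#' @slot rowScores named numeric vector, one score per row.
#'
#' @seealso [leverageScores()], [topLeverage()]
#' @export
setClass("LeverageScores",
  representation(k = "integer", columnScores = "numeric", rowScores = "numeric"))

setValidity("LeverageScores", function(object) {
  msg <- character()
  k <- object@k
  if (length(k) != 1L || k < 1L) msg <- c(msg, "k must be a positive integer")
  for (axis in c("columnScores", "rowScores")) {
    s <- slot(object, axis)
    if (length(s)) {
      if (abs(sum(s) - 1) > 1e-8)
        msg <- c(msg, paste(axis, "must sum to 1"))
      if (any(s < -1e-12) || any(s > 1 / k + 1e-12))
        msg <- c(msg, paste(axis, "must lie in [0, 1/k]"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Result of a column or row selection strategy
#'
#' Records which indices one selection strategy picked along one axis,
#' together with the leverage scores it consulted, the sampling
#' probabilities (for the randomized strategies), and the strategy name.
#'
#' @slot axis either \code{"columns"} or \code{"rows"}.
#' @slot indices integer vector of distinct selected positions (1-based),
#'   in strategy-defined order (score order for the deterministic
#'   strategies, ascending for the randomized ones).
#' @slot names character vector of the corresponding dimension names.
#' @slot probabilities the per-index sampling probabilities
#'   \code{min(1, c * score)} used by the randomized strategies, or
#'   \code{NULL} for the deterministic ones.
#' @slot scores the full leverage-score vector along the axis.
#' @slot method the strategy name, one of \code{"random"},
#'   \code{"exact.num.random"}, \code{"top.scores"},
#'   \code{"ortho.top.scores"}, \code{"highest.ranks"}.
#' @slot spanFilled logical; \code{TRUE} when \code{ortho.top.scores} ran
#'   out of directions outside the selected span and filled the remaining
#'   slots by raw leverage score.
#'
#' @export
setClass("FeatureSelection",
  representation(axis = "character", indices = "integer", names = "character",
    probabilities = "numericOrNULL", scores = "numeric",
    method = "character", spanFilled = "logical"),
  prototype(probabilities = NULL, spanFilled = FALSE))

setValidity("FeatureSelection", function(object) {
  msg <- character()
  if (!object@axis %in% c("columns", "rows"))
    msg <- c(msg, "axis must be 'columns' or 'rows'")
  idx <- object@indices
  if (anyDuplicated(idx)) msg <- c(msg, "indices must be distinct")
  if (length(idx) && (min(idx) < 1L || max(idx) > length(object@scores)))
    msg <- c(msg, "indices out of bounds")
  if (length(object@names) != length(idx))
    msg <- c(msg, "names must parallel indices")
  if (length(msg)) msg else TRUE
})

#' A CUR decomposition of a data matrix
#'
#' The result of \code{\link{cur}}: the factor \code{C} (actual columns of
#' the input), the linking matrix \code{U}, and either the factor \code{R}
#' (actual rows) or, in restricted mode, no \code{R} -- there
#' \code{U = pinv(C)} and the coefficient matrix \code{X = U \%*\% A} is
#' computed only on demand by \code{\link{getX}}, never stored.
#'
#' @slot C matrix of selected columns, in selection order.
#' @slot U linking matrix; \code{pinv(C) A pinv(R)} in full mode,
#'   \code{pinv(C)} in restricted mode.
#' @slot R matrix of selected rows, or \code{NULL} in restricted mode.
#' @slot columnSelection,rowSelection \linkS4class{FeatureSelection}
#'   objects (\code{rowSelection} is \code{NULL} in restricted mode).
#' @slot leverage the \linkS4class{LeverageScores} used for selection.
#' @slot k integer rank parameter at which leverage was computed.
#' @slot relativeError relative Frobenius approximation error
#'   \code{||A - CUR||_F / ||A||_F}, or \code{NULL} if not requested.
#' @slot restricted logical flag for the one-sided form.
#'
#' @seealso [cur()], [getC()], [getU()], [getR()], [getX()]
#' @export
setClass("CURDecomposition",
  representation(C = "matrix", U = "matrix", R = "matrixOrNULL",
    columnSelection = "FeatureSelection", rowSelection = "ANY",
    leverage = "LeverageScores", k = "integer",
    relativeError = "numericOrNULL", restricted = "logical"),
  prototype(R = NULL, rowSelection = NULL, relativeError = NULL,
    restricted = FALSE))

setValidity("CURDecomposition", function(object) {
  msg <- character()
  if (ncol(object@C) != length(object@columnSelection@indices))
    msg <- c(msg, "C must have one column per selected index")
  if (object@restricted) {
    if (!is.null(object@R)) msg <- c(msg, "restricted mode stores no R")
  } else {
    if (is.null(object@R) || is.null(object@rowSelection))
      msg <- c(msg, "full mode requires R and a row selection")
  }
  if (!is.null(object@relativeError) && object@relativeError < -1e-12)
    msg <- c(msg, "relativeError must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Data underlying a leverage-score plot
#'
#' Scores in original feature order, the indices of the top scores to
#' highlight, and the uniform level \code{1/n} that scores would take if
#' every feature were equally influential.
#'
#' @slot scores named numeric vector in original order.
#' @slot highlighted integer indices of the top-scoring features.
#' @slot uniformLevel numeric, \code{1/length(scores)}.
#' @slot axis the axis the scores belong to.
#'
#' @seealso [leveragePlotData()], [plotLeverage()]
#' @export
setClass("LeveragePlotData",
  representation(scores = "numeric", highlighted = "integer",
    uniformLevel = "numeric", axis = "character"))

setValidity("LeveragePlotData", function(object) {
  msg <- character()
  n <- length(object@scores)
  if (length(object@highlighted) &&
      (min(object@highlighted) < 1L || max(object@highlighted) > n))
    msg <- c(msg, "highlighted indices out of bounds")
  if (abs(object@uniformLevel - 1 / n) > 1e-12)
    msg <- c(msg, "uniformLevel must equal 1/length(scores)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TruncatedSVD", function(object) {
  cat("TruncatedSVD: ", nrow(object@u), " x ", nrow(object@v),
      " matrix, ", object@p, " triplet(s) retained\n", sep = "")
  cat("  singular values: ",
      paste(signif(utils::head(object@d, 5L), 4), collapse = ", "),
      if (length(object@d) > 5L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "LeverageScores", function(object) {
  cat("LeverageScores at k = ", object@k, ": ",
      length(object@rowScores), " row score(s), ",
      length(object@columnScores), " column score(s)\n", sep = "")
  top <- utils::head(sort(object@columnScores, decreasing = TRUE), 3L)
  cat("  top column scores: ",
      paste(names(top), signif(top, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "FeatureSelection", function(object) {
  cat("FeatureSelection (", object@method, ") of ",
      length(object@indices), " ", object@axis, "\n", sep = "")
  cat("  indices: ",
      paste(utils::head(object@indices, 10L), collapse = ", "),
      if (length(object@indices) > 10L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "CURDecomposition", function(object) {
  cat("CURDecomposition (k = ", object@k,
      if (object@restricted) ", restricted" else "", ")\n", sep = "")
  cat("  C: ", nrow(object@C), " x ", ncol(object@C), "\n", sep = "")
  cat("  U: ", nrow(object@U), " x ", ncol(object@U), "\n", sep = "")
  if (!is.null(object@R))
    cat("  R: ", nrow(object@R), " x ", ncol(object@R), "\n", sep = "")
  if (!is.null(object@relativeError))
    cat("  relative error: ", signif(object@relativeError, 6), "\n", sep = "")
})
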