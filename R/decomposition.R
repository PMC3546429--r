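#' Moore-Penrose pseudoinverse
#'
#' Computed from the SVD, inverting only singular values above the
#' standard cutoff \code{max(dim(M)) * .Machine$double.eps * max(d)},
#' so rank-deficient inputs (e.g. a C factor containing correlated
#' columns) are handled without blow-up. Satisfies the four Penrose
#' conditions to numerical precision.
#'
#' @param M a real matrix.
#' @return The pseudoinverse, with dimensions \code{ncol(M) x nrow(M)}.
#' @examples
#' pinv(matrix(c(2, 0, 0, 0), 2))
#' @export
pinv <- function(M) {
  if (!is.matrix(M) || !is.numeric(M) || !all(is.finite(M)))
    stop("M must be a finite numeric matrix", call. = FALSE)
  s <- svd(M)
  if (!length(s$d) || s$d[1L] == 0)
    return(matrix(0, ncol(M), nrow(M)))
  tol <- max(dim(M)) * .Machine$double.eps * s$d[1L]
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

.frobenius <- function(M) sqrt(sum(M^2))

# new("CURDecomposition", C = ...) would partially match new()'s Class
# formal; build empty and fill slots instead.
.newCUR <- function(C, U, R, columnSelection, rowSelection, lev,
                    restricted) {
  out <- new("CURDecomposition")
  out@C <- C
  out@U <- U
  out@R <- R
  out@columnSelection <- columnSelection
  out@rowSelection <- rowSelection
  out@leverage <- lev
  out@k <- lev@k
  out@restricted <- restricted
  validObject(out)
  out
}

.selectionMatrix <- function(A, sel, axis) {
  if (!length(sel@indices))
    stop("empty ", axis, " selection", call. = FALSE)
  if (axis == "columns") A[, sel@indices, drop = FALSE]
  else A[sel@indices, , drop = FALSE]
}

#' Assemble a full CUR decomposition from selections
#'
#' Extracts \code{C} (the selected actual columns) and \code{R} (the
#' selected actual rows) and links them with \code{U = pinv(C) A
#' pinv(R)}, the choice that makes \code{CUR} the best approximation to
#' \code{A} within the span of the selected columns and rows.
#'
#' @param A the data matrix.
#' @param cols,rows \linkS4class{FeatureSelection} objects for the two
#'   axes.
#' @param lev the \linkS4class{LeverageScores} used (stored for
#'   provenance).
#' @param computeError if \code{TRUE}, attach the relative Frobenius
#'   error \code{||A - CUR||_F / ||A||_F}.
#' @return A \linkS4class{CURDecomposition}.
#' @export
buildCUR <- function(A, cols, rows, lev, computeError = FALSE) {
  A <- asDataMatrix(A)
  C <- .selectionMatrix(A, cols, "columns")
  R <- .selectionMatrix(A, rows, "rows")
  U <- pinv(C) %*% A %*% pinv(R)
  out <- .newCUR(C, U, R, cols, rows, lev, restricted = FALSE)
  if (computeError) out@relativeError <- approximationError(A, out)
  out
}

#' Assemble a restricted (one-sided) decomposition
#'
#' The restricted form approximates \code{A} by its orthogonal
#' projection onto the span of the selected columns: \code{A ~ P_C A =
#' C X} with \code{X = pinv(C) A}. Only \code{U = pinv(C)} is stored;
#' the product \code{X = U A} is not performed here -- use
#' \code{\link{getX}} when the coefficients are actually needed.
#'
#' @inheritParams buildCUR
#' @return A restricted \linkS4class{CURDecomposition} (no \code{R}).
#' @export
buildRestricted <- function(A, cols, lev, computeError = FALSE) {
  A <- asDataMatrix(A)
  C <- .selectionMatrix(A, cols, "columns")
  out <- .newCUR(C, pinv(C), NULL, cols, NULL, lev, restricted = TRUE)
  if (computeError) out@relativeError <- approximationError(A, out)
  out
}

#' Relative approximation error of a decomposition
#'
#' Returns \code{||A - CUR||_F / ||A||_F} (restricted mode:
#' \code{||A - CX||_F / ||A||_F}). By the Eckart-Young theorem this can
#' never fall below the error of the best rank-\code{s} SVD truncation,
#' where \code{s} is the rank of the reconstruction.
#'
#' @param A the data matrix the decomposition was built from.
#' @param result a \linkS4class{CURDecomposition}.
#' @return Non-negative scalar.
#' @export
approximationError <- function(A, result) {
  A <- asDataMatrix(A)
  stopifnot(is(result, "CURDecomposition"))
  nA <- .frobenius(A)
  if (nA == 0)
    stop("A is the zero matrix; relative error is undefined", call. = FALSE)
  approx <- if (result@restricted)
    result@C %*% (result@U %*% A)
  else
    result@C %*% result@U %*% result@R
  .frobenius(A - approx) / nA
}

#' CUR matrix decomposition
#'
#' The top-level entry point: computes the statistical leverage scores
#' of \code{A} at rank \code{k}, selects \code{c} columns and \code{r}
#' rows by the requested strategy, and assembles the factors. With
#' \code{r = "all"} row selection is skipped and the restricted
#' one-sided form \code{A ~ C X} is returned instead.
#'
#' The rank parameter \code{k} governs which structure the leverage
#' scores (and hence the selection) target and should be chosen on
#' domain grounds; if omitted it is set by the spectrum rule of
#' [defaultRank()]: the smallest \code{k} whose top singular values sum
#' to more than 80% of the total.
#'
#' @param A numeric matrix with (optional) row and column names; missing
#'   names are auto-assigned from indices.
#' @param c number of columns to select.
#' @param r number of rows to select, or \code{"all"} for the
#'   restricted decomposition.
#' @param k rank parameter, or \code{NULL} for the 80% spectrum rule.
#' @param method selection strategy; see [selectFeatures()].
#' @param seed optional integer seed for the randomized strategies
#'   (ignored by the deterministic ones); the caller's RNG state is
#'   left untouched.
#' @param computeError if \code{TRUE}, attach the relative Frobenius
#'   approximation error.
#' @return A \linkS4class{CURDecomposition}.
#' @examples
#' A <- matrix(rnorm(80), 10, 8)
#' res <- cur(A, c = 4, r = 4, k = 2, method = "top.scores",
#'            computeError = TRUE)
#' getC(res)[1:3, ]
#' relativeError(res)
#' @export
cur <- function(A, c, r = "all", k = NULL, method = CUR_METHODS,
                seed = NULL, computeError = FALSE) {
  method <- match.arg(method)
  A <- asDataMatrix(A)
  s <- truncatedSVD(A, min(dim(A)))
  if (is.null(k)) k <- defaultRank(s@d)
  k <- .checkCount(k, min(dim(A)), "k")
  lev <- leverageScores(s, k)
  sel <- selectFeatures(A, lev, method, c = c, r = r, seed = seed)
  if (is.null(sel$rows))
    buildRestricted(A, sel$columns, lev, computeError = computeError)
  else
    buildCUR(A, sel$columns, sel$rows, lev, computeError = computeError)
}

#' @describeIn getC method for CURDecomposition.
#' @export
setMethod("getC", "CURDecomposition", function(object) object@C)

#' @describeIn getU method for CURDecomposition.
#' @export
setMethod("getU", "CURDecomposition", function(object) object@U)

#' @describeIn getR method for CURDecomposition.
#' @export
setMethod("getR", "CURDecomposition", function(object) {
  if (object@restricted)
    stop("restricted decomposition has no R factor; use getX()",
         call. = FALSE)
  object@R
})

#' @describeIn getX method for CURDecomposition.
#' @export
setMethod("getX", "CURDecomposition", function(object, A) {
  if (!object@restricted)
    stop("X is defined for restricted decompositions; use getU()/getR()",
         call. = FALSE)
  object@U %*% asDataMatrix(A)
})

#' @describeIn leverage Scores stored in a decomposition.
#' @export
setMethod("leverage", "CURDecomposition", function(object,
    axis = c("columns", "rows")) {
  leverage(object@leverage, match.arg(axis))
})

#' @describeIn topLeverage Top features of a decomposition's scores.
#' @export
setMethod("topLeverage", "CURDecomposition", function(object, count,
    axis = c("columns", "rows")) {
  topLeverage(object@leverage, count, match.arg(axis))
})

#' @describeIn relativeError method for CURDecomposition.
#' @export
setMethod("relativeError", "CURDecomposition",
          function(object) object@relativeError)

#' @describeIn isRestricted method for CURDecomposition.
#' @export
setMethod("isRestricted", "CURDecomposition",
          function(object) object@restricted)
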