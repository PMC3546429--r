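#' Extract the C factor (selected columns)
#'
#' @param object a \linkS4class{CURDecomposition}.
#' @return The matrix of selected columns, in selection order, with
#'   column names carried over from the input matrix.
#' @export
setGeneric("getC", function(object) standardGeneric("getC"))

#' Extract the U linking matrix
#'
#' @param object a \linkS4class{CURDecomposition}.
#' @return In full mode \code{pinv(C) A pinv(R)}; in restricted mode
#'   \code{pinv(C)}, so that \code{X = U A}.
#' @export
setGeneric("getU", function(object) standardGeneric("getU"))

#' Extract the R factor (selected rows)
#'
#' @param object a \linkS4class{CURDecomposition}.
#' @return The matrix of selected rows, or an error in restricted mode.
#' @export
setGeneric("getR", function(object) standardGeneric("getR"))

#' Compute the coefficient matrix X of a restricted decomposition
#'
#' In restricted mode \code{A} is approximated by its projection onto the
#' span of the selected columns, \code{A ~ C X} with \code{X = pinv(C) A}.
#' \code{X} is never stored in the object; this accessor performs the
#' multiplication \code{U A} on demand.
#'
#' @param object a restricted \linkS4class{CURDecomposition}.
#' @param A the original data matrix the decomposition was built from.
#' @return The matrix \code{X = pinv(C) A}.
#' @export
setGeneric("getX", function(object, A) standardGeneric("getX"))

#' Extract leverage scores
#'
#' @param object a \linkS4class{CURDecomposition} or
#'   \linkS4class{LeverageScores} object.
#' @param axis \code{"columns"} or \code{"rows"}.
#' @return Named numeric vector of normalized leverage scores along the
#'   requested axis.
#' @export
setGeneric("leverage", function(object, axis = c("columns", "rows"))
  standardGeneric("leverage"))

#' Indices and names of the highest-leverage features
#'
#' Ranks features by leverage score (descending, ties broken by ascending
#' index) and returns the top \code{count}, for subsetting the original
#' matrix to its most influential columns or rows.
#'
#' @param object a \linkS4class{CURDecomposition} or
#'   \linkS4class{LeverageScores} object.
#' @param count number of features to return.
#' @param axis \code{"columns"} or \code{"rows"}.
#' @return A data.frame with columns \code{name}, \code{index},
#'   \code{score}, ordered by descending score.
#' @export
setGeneric("topLeverage",
  function(object, count, axis = c("columns", "rows"))
    standardGeneric("topLeverage"))

#' Relative approximation error of a decomposition
#'
#' @param object a \linkS4class{CURDecomposition}.
#' @return \code{||A - CUR||_F / ||A||_F} if it was computed at build
#'   time, otherwise \code{NULL}; see [approximationError()] to compute
#'   it afterwards.
#' @export
setGeneric("relativeError", function(object) standardGeneric("relativeError"))

#' Is a decomposition in restricted (one-sided) form?
#'
#' @param object a \linkS4class{CURDecomposition}.
#' @return \code{TRUE} when row selection was skipped and the object
#'   represents \code{A ~ C X}.
#' @export
setGeneric("isRestricted", function(object) standardGeneric("isRestricted"))
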