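CUR_METHODS <- c("random", "exact.num.random", "top.scores",
                 "ortho.top.scores", "highest.ranks")

.newSelection <- function(axis, indices, scores, method,
                          probabilities = NULL, spanFilled = FALSE) {
  nm <- names(scores)
  if (is.null(nm)) nm <- as.character(seq_along(scores))
  new("FeatureSelection", axis = axis, indices = as.integer(indices),
      names = nm[indices], probabilities = probabilities,
      scores = unname(scores), method = method, spanFilled = spanFilled)
}

#' Randomized ColumnSelect sampling
#'
#' The original randomized selection: index \code{j} is kept by an
#' independent Bernoulli draw with probability \code{p_j}, so only the
#' expected number of selections -- \code{sum(p)} -- is controlled, not
#' the realized count. An empty draw is retried (fresh draws from the
#' same stream) up to 100 times before failing.
#'
#' @param probabilities inclusion probabilities in \code{[0, 1]},
#'   typically from [samplingProbabilities()].
#' @param seed optional integer seed; the caller's RNG state is restored
#'   afterwards. \code{NULL} draws from the current stream.
#' @param axis which axis the indices refer to.
#' @param scores the leverage scores that produced the probabilities
#'   (stored for provenance; defaults to the probabilities themselves).
#' @return A \linkS4class{FeatureSelection} with indices in ascending
#'   order.
#' @export
selectRandom <- function(probabilities, seed = NULL,
                         axis = c("columns", "rows"),
                         scores = probabilities) {
  axis <- match.arg(axis)
  p <- probabilities
  if (any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (all(p <= 0))
    stop("all selection probabilities are zero; nothing can be selected",
         call. = FALSE)
  keep <- .withSeed(seed, {
    k <- integer(0)
    for (attempt in seq_len(100L)) {
      k <- which(stats::runif(length(p)) < p)
      if (length(k)) break
    }
    k
  })
  if (!length(keep))
    stop("random selection returned no indices after 100 draws",
         call. = FALSE)
  .newSelection(axis, keep, scores, "random", probabilities = unname(p))
}

#' Exact-count weighted random selection
#'
#' Like the randomized sampler, but guarantees that exactly \code{count}
#' distinct indices are returned: a weighted draw without replacement
#' with weights \code{min(1, count * score_j)}, preserving the
#' importance weighting of ColumnSelect while fixing the output size.
#'
#' @param scores non-negative leverage scores, not all zero.
#' @param count number of indices to select.
#' @inheritParams selectRandom
#' @return A \linkS4class{FeatureSelection} with exactly \code{count}
#'   indices in ascending order.
#' @export
selectExactNumRandom <- function(scores, count, seed = NULL,
                                 axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  count <- .checkCount(count, length(scores), "count")
  if (any(scores < -1e-12))
    stop("scores must be non-negative", call. = FALSE)
  w <- pmin(1, count * scores)
  if (sum(w > 0) < count)
    stop("fewer strictly positive weights than requested selections",
         call. = FALSE)
  keep <- .withSeed(seed,
    sort(sample(seq_along(w), size = count, replace = FALSE, prob = w)))
  .newSelection(axis, keep, scores, "exact.num.random",
                probabilities = unname(w))
}

#' Deterministic top-score selection
#'
#' Returns the \code{count} indices with the largest leverage scores,
#' ordered by descending score with ties broken by ascending index.
#' Using the scores as a ranking function rather than a sampling
#' distribution makes feature selection fully reproducible.
#'
#' @inheritParams selectExactNumRandom
#' @return A \linkS4class{FeatureSelection} in descending-score order.
#' @examples
#' selectTopScores(c(a = 0.1, b = 0.4, c = 0.2, d = 0.3), 2)
#' @export
selectTopScores <- function(scores, count, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  count <- .checkCount(count, length(scores), "count")
  ord <- order(-scores, seq_along(scores))[seq_len(count)]
  .newSelection(axis, ord, scores, "top.scores")
}

#' Greedy leverage-and-orthogonality selection
#'
#' Selects features one at a time, rescoring the remaining candidates at
#' each step by the product of their leverage score and the fraction of
#' their vector that lies outside the span of the already-selected
#' features: \code{score_j * ||(I - P_S) a_j|| / ||a_j||}. A feature
#' nearly identical to one already chosen contributes almost no new
#' direction and is demoted, which is the point of this strategy on
#' data with highly correlated columns or rows. If every remaining
#' candidate lies (numerically) inside the selected span before
#' \code{count} is reached, the remaining slots are filled by raw
#' leverage score and the result is flagged via the \code{spanFilled}
#' slot.
#'
#' @param A the data matrix the scores were computed from.
#' @inheritParams selectExactNumRandom
#' @return A \linkS4class{FeatureSelection} in pick order.
#' @export
selectOrthoTopScores <- function(A, scores, count,
                                 axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  A <- asDataMatrix(A)
  M <- if (axis == "columns") A else t(A)
  if (length(scores) != ncol(M))
    stop("scores length does not match the selected axis", call. = FALSE)
  count <- .checkCount(count, ncol(M), "count")
  tol <- 1e-10
  colNorms <- sqrt(colSums(M^2))

  idx <- seq_len(ncol(M))
  sel <- order(-scores, idx)[1L]
  Q <- matrix(0, nrow(M), 0L)
  if (colNorms[sel] > tol) Q <- cbind(Q, M[, sel] / colNorms[sel])
  spanFilled <- FALSE

  while (length(sel) < count) {
    rest <- setdiff(idx, sel)
    resid <- M[, rest, drop = FALSE]
    if (ncol(Q)) resid <- resid - Q %*% (t(Q) %*% resid)
    frac <- sqrt(colSums(resid^2)) /
      ifelse(colNorms[rest] > 0, colNorms[rest], 1)
    cand <- ifelse(colNorms[rest] > 0, scores[rest] * frac, 0)
    if (max(cand) <= tol) {
      spanFilled <- TRUE
      fill <- rest[order(-scores[rest], rest)]
      sel <- c(sel, fill[seq_len(count - length(sel))])
      break
    }
    pick <- rest[order(-cand, rest)[1L]]
    r <- M[, pick] - if (ncol(Q)) Q %*% (t(Q) %*% M[, pick]) else 0
    rn <- sqrt(sum(r^2))
    if (rn > tol * max(colNorms[pick], 1)) Q <- cbind(Q, r / rn)
    sel <- c(sel, pick)
  }
  .newSelection(axis, sel, scores, "ortho.top.scores",
                spanFilled = spanFilled)
}

#' Best-rank-across-k selection
#'
#' Computes leverage scores at every rank parameter \code{k' = 1..k} and
#' ranks the features at each (rank 1 = highest score, ties by ascending
#' index). A feature's merit is its best rank attained at any \code{k'},
#' so features that dominate the spectrum at some -- possibly small --
#' rank are favoured. The \code{count} features with the best merit are
#' returned; ties are broken by the rank at \code{k' = k}, then by
#' ascending index.
#'
#' @param A the data matrix.
#' @param k maximum rank parameter tried.
#' @param count number of indices to select.
#' @param axis which axis to select along.
#' @return A \linkS4class{FeatureSelection}; the stored scores are the
#'   leverage scores at rank \code{k}.
#' @export
selectHighestRanks <- function(A, k, count, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  A <- asDataMatrix(A)
  s <- truncatedSVD(A, min(dim(A)))
  k <- .checkCount(k, s@p, "k")
  V <- if (axis == "columns") s@v else s@u
  n <- nrow(V)
  count <- .checkCount(count, n, "count")
  idx <- seq_len(n)

  merit <- rep.int(n, n)
  rankAtK <- integer(n)
  cum <- numeric(n)
  for (kp in seq_len(k)) {
    cum <- cum + V[, kp]^2
    rp <- integer(n)
    rp[order(-cum, idx)] <- idx  # leverage at kp is cum/kp; order unchanged
    merit <- pmin(merit, rp)
    if (kp == k) rankAtK <- rp
  }
  sel <- order(merit, rankAtK, idx)[seq_len(count)]
  scores <- cum / k
  names(scores) <- if (axis == "columns") colnames(A) else rownames(A)
  .newSelection(axis, sel, scores, "highest.ranks")
}

#' Select columns (and rows) by a named strategy
#'
#' Dispatcher over the five selection strategies. Column selection uses
#' the column leverage scores; row selection uses the row scores (which
#' is equivalent to running the same strategy on the transpose). Setting
#' \code{r = "all"} skips row selection entirely, yielding the input for
#' the restricted one-sided decomposition.
#'
#' @param A the data matrix.
#' @param lev a \linkS4class{LeverageScores} for \code{A}; its rank
#'   \code{k} is the one used by \code{highest.ranks}.
#' @param method one of \code{"random"}, \code{"exact.num.random"},
#'   \code{"top.scores"}, \code{"ortho.top.scores"},
#'   \code{"highest.ranks"}.
#' @param c number of columns to select (expected number for
#'   \code{"random"}).
#' @param r number of rows to select, or \code{"all"} to skip row
#'   selection.
#' @param seed optional seed covering both axes' random draws.
#' @return A list with elements \code{columns} (a
#'   \linkS4class{FeatureSelection}) and \code{rows} (a
#'   \linkS4class{FeatureSelection}, or \code{NULL} when
#'   \code{r = "all"}).
#' @export
selectFeatures <- function(A, lev, method = CUR_METHODS, c, r = "all",
                           seed = NULL) {
  method <- match.arg(method)
  A <- asDataMatrix(A)
  stopifnot(is(lev, "LeverageScores"))
  restricted <- identical(r, "all")
  .withSeed(seed, {
    cols <- .selectAxis(A, lev, method, c, "columns")
    rows <- if (restricted) NULL else .selectAxis(A, lev, method, r, "rows")
    list(columns = cols, rows = rows)
  })
}

.selectAxis <- function(A, lev, method, count, axis) {
  scores <- leverage(lev, axis)
  switch(method,
    random = selectRandom(samplingProbabilities(scores, count),
                          axis = axis, scores = scores),
    exact.num.random = selectExactNumRandom(scores, count, axis = axis),
    top.scores = selectTopScores(scores, count, axis = axis),
    ortho.top.scores = selectOrthoTopScores(A, scores, count, axis = axis),
    highest.ranks = selectHighestRanks(A, lev@k, count, axis = axis))
}
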