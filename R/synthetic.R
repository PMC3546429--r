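#' Synthetic low-rank-plus-noise matrix
#'
#' Generates a seeded test matrix with known structure: the product of
#' Gaussian factors of the requested rank, optional additive Gaussian
#' noise, and optionally a set of planted columns constructed to be
#' orthogonal to the signal span (and to each other), scaled to the
#' mean signal column norm. Planted columns carry their own singular
#' directions, so at rank \code{rank + nPlanted} they attain leverage
#' scores near the \code{1/k} maximum and are recoverable by
#' \code{top.scores} -- the ground truth used by the package's
#' recovery tests.
#'
#' @param m,n dimensions of the signal block (the output has
#'   \code{n + nPlanted} columns).
#' @param rank rank of the signal block.
#' @param noiseSd standard deviation of the additive Gaussian noise
#'   (applied to the whole matrix, planted columns included).
#' @param nPlanted number of planted orthogonal columns, appended last
#'   and named \code{planted1, planted2, ...}.
#' @param seed optional integer seed; the caller's RNG state is
#'   restored.
#' @return Named numeric matrix of size \code{m x (n + nPlanted)}.
#' @examples
#' A <- generateLowRank(30, 20, rank = 3, noiseSd = 0, seed = 1)
#' @export
generateLowRank <- function(m = 60, n = 40, rank = 4, noiseSd = 0.1,
                            nPlanted = 0, seed = NULL) {
  rank <- .checkCount(rank, min(m, n), "rank")
  if (nPlanted > m - rank)
    stop("cannot plant more orthogonal columns than the null space holds",
         call. = FALSE)
  .withSeed(seed, {
    L <- matrix(stats::rnorm(m * rank), m, rank)
    f <- matrix(stats::rnorm(rank * n), rank, n)
    S <- L %*% f
    if (nPlanted > 0) {
      basis <- qr.Q(qr(L))
      scale <- mean(sqrt(colSums(S^2)))
      P <- matrix(0, m, nPlanted)
      for (j in seq_len(nPlanted)) {
        v <- stats::rnorm(m)
        v <- v - basis %*% (t(basis) %*% v)
        if (j > 1L) {
          Pj <- P[, seq_len(j - 1L), drop = FALSE]
          v <- v - Pj %*% (t(Pj) %*% v) / scale^2
        }
        P[, j] <- scale * v / sqrt(sum(v^2))
      }
      S <- cbind(S, P)
    }
    A <- S + if (noiseSd > 0)
      matrix(stats::rnorm(m * ncol(S), sd = noiseSd), m, ncol(S)) else 0
    dimnames(A) <- list(paste0("row", seq_len(m)),
      c(paste0("col", seq_len(n)),
        if (nPlanted > 0) paste0("planted", seq_len(nPlanted))))
    A
  })
}

#' Synthetic grouped expression matrix
#'
#' Emulates a features x samples expression study with a small set of
#' group-informative features: a Gaussian noise baseline on which the
#' first \code{nInformative} features receive group-specific,
#' sample-mean-zero shifts of magnitude \code{effect}. Informative
#' feature \code{i} is assigned to group \code{1 + (i - 1) %%
#' nGroups} (round-robin) and shifted by \code{effect * (1 - n_g/n)}
#' in that group's samples and \code{-effect * n_g/n} elsewhere. The
#' shift structure spans \code{nGroups - 1} dimensions, so the
#' informative features dominate the leverage scores at rank
#' \code{nGroups - 1} once \code{effect} exceeds the noise.
#'
#' Defaults mirror a soft-tissue-tumor microarray study: 5520 features,
#' 31 samples in 3 phenotype groups, 27 informative features.
#'
#' @param nFeatures number of features (rows).
#' @param groupSizes integer vector of samples per group; the sample
#'   count is \code{sum(groupSizes)}.
#' @param nInformative number of group-informative features (placed
#'   first, named \code{gene1..}).
#' @param effect magnitude of the group mean shift.
#' @param noiseSd baseline Gaussian noise standard deviation.
#' @param seed optional integer seed.
#' @return A list with elements \code{matrix} (features x samples),
#'   \code{labels} (per-sample group names \code{group1, ...}) and
#'   \code{informative} (row indices of the informative features).
#' @export
generateGroupedExpression <- function(nFeatures = 5520,
                                      groupSizes = c(11, 10, 10),
                                      nInformative = 27, effect = 2,
                                      noiseSd = 1, seed = NULL) {
  groupSizes <- as.integer(groupSizes)
  if (any(groupSizes < 1L)) stop("group sizes must be positive", call. = FALSE)
  nSamples <- sum(groupSizes)
  nGroups <- length(groupSizes)
  if (nInformative > nFeatures)
    stop("more informative features than features", call. = FALSE)
  labels <- rep(paste0("group", seq_len(nGroups)), times = groupSizes)
  .withSeed(seed, {
    A <- matrix(stats::rnorm(nFeatures * nSamples, sd = noiseSd),
                nFeatures, nSamples)
    if (nInformative > 0) {
      for (i in seq_len(nInformative)) {
        g <- 1L + (i - 1L) %% nGroups
        inG <- labels == paste0("group", g)
        A[i, ] <- A[i, ] + effect * (inG - groupSizes[g] / nSamples)
      }
    }
    dimnames(A) <- list(paste0("gene", seq_len(nFeatures)),
                        paste0("sample", seq_len(nSamples)))
    list(matrix = A, labels = labels,
         informative = seq_len(nInformative))
  })
}
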