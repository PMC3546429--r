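# Seeded dense test matrix with names.
seededMatrix <- function(m, n, seed) {
  set.seed(seed)
  matrix(rnorm(m * n), m, n,
         dimnames = list(paste0("r", seq_len(m)), paste0("c", seq_len(n))))
}

# Exact-rank-s matrix from an outer product of Gaussian factors.
exactRankMatrix <- function(m, n, s, seed) {
  set.seed(seed)
  L <- matrix(rnorm(m * s), m, s)
  f <- matrix(rnorm(s * n), s, n)
  out <- L %*% f
  dimnames(out) <- list(paste0("r", seq_len(m)), paste0("c", seq_len(n)))
  out
}

# Independent leverage oracle: eigenvectors of the Gram matrix give the
# right singular vectors; the hat-matrix diagonal is sign-invariant.
hatDiagOracle <- function(A, k, axis = "columns") {
  G <- if (axis == "columns") crossprod(A) else tcrossprod(A)
  V <- eigen(G, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  diag(V %*% t(V)) / k
}

# Brute-force separation oracle: explicit double loop over every
# cross-group point pair.
bruteSeparation <- function(points, labels) {
  groups <- unique(labels)
  if (length(groups) < 2) return(0)
  total <- 0
  for (i in seq_len(length(groups) - 1)) {
    for (j in seq.int(i + 1, length(groups))) {
      P <- points[labels == groups[i], , drop = FALSE]
      Q <- points[labels == groups[j], , drop = FALSE]
      d <- numeric(0)
      for (a in seq_len(nrow(P)))
        for (b in seq_len(nrow(Q)))
          d <- c(d, sqrt(sum((P[a, ] - Q[b, ])^2)))
      total <- total + median(d)
    }
  }
  total
}

# Build a FeatureSelection by hand for decomposition tests.
manualSelection <- function(indices, n, axis = "columns",
                            method = "top.scores") {
  scores <- rep(1 / n, n)
  names(scores) <- paste0(if (axis == "columns") "c" else "r", seq_len(n))
  new("FeatureSelection", axis = axis, indices = as.integer(indices),
      names = names(scores)[indices], probabilities = NULL,
      scores = unname(scores), method = method, spanFilled = FALSE)
}

# Rank of a matrix at a relative tolerance, via its spectrum.
numericalRank <- function(M, tol = 1e-8) {
  d <- svd(M, nu = 0, nv = 0)$d
  sum(d > tol * max(d[1], .Machine$double.eps))
}
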