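test_that("pinv satisfies the Penrose conditions and matches oracles", {
  expect_equal(pinv(matrix(c(2, 0, 0, 0), 2)),
               matrix(c(0.5, 0, 0, 0), 2))
  M <- seededMatrix(4, 4, seed = 2)
  expect_equal(pinv(M), solve(M), tolerance = 1e-8, ignore_attr = TRUE)

  N <- unname(seededMatrix(6, 3, seed = 3))
  Np <- pinv(N)
  expect_equal(N %*% Np %*% N, N, tolerance = 1e-8)
  expect_equal(Np %*% N %*% Np, Np, tolerance = 1e-8)
  expect_equal(t(N %*% Np), N %*% Np, tolerance = 1e-8)
  expect_equal(t(Np %*% N), Np %*% N, tolerance = 1e-8)
  expect_equal(Np, MASS::ginv(N), tolerance = 1e-8)

  # rank-deficient input: small singular values are zeroed, not inverted
  D <- exactRankMatrix(5, 5, s = 2, seed = 4)
  expect_equal(D %*% pinv(D) %*% D, D, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("CUR recovers exactly when selections span a low-rank matrix", {
  A <- exactRankMatrix(4, 4, s = 2, seed = 7)
  lev <- leverageScores(A, 2)
  res <- buildCUR(A, manualSelection(c(1, 2), 4, "columns"),
                  manualSelection(c(1, 2), 4, "rows"), lev,
                  computeError = TRUE)
  expect_lt(res@relativeError, 1e-8)
})

test_that("full selections reproduce the matrix", {
  A <- seededMatrix(6, 5, seed = 9)
  lev <- leverageScores(A, 2)
  res <- buildCUR(A, manualSelection(1:5, 5, "columns"),
                  manualSelection(1:6, 6, "rows"), lev,
                  computeError = TRUE)
  expect_lt(res@relativeError, 1e-8)
  expect_equal(getC(res) %*% getU(res) %*% getR(res), A,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the linking matrix matches an independent pseudoinverse oracle", {
  A <- seededMatrix(10, 8, seed = 10)
  cols <- manualSelection(c(2, 5, 7), 8, "columns")
  rows <- manualSelection(c(1, 4, 9), 10, "rows")
  res <- buildCUR(A, cols, rows, leverageScores(A, 3))
  C <- A[, cols@indices]
  R <- A[rows@indices, ]
  expect_equal(getU(res), MASS::ginv(C) %*% A %*% MASS::ginv(R),
               tolerance = 1e-8, ignore_attr = TRUE)
  # C and R are exact copies of the selected columns/rows
  expect_identical(getC(res), A[, cols@indices])
  expect_identical(getR(res), A[rows@indices, ])
})

test_that("restricted decomposition equals the orthogonal projection", {
  A <- seededMatrix(8, 6, seed = 12)
  cols <- manualSelection(c(1, 3, 5), 6, "columns")
  res <- buildRestricted(A, cols, leverageScores(A, 3),
                         computeError = TRUE)
  expect_true(isRestricted(res))
  X <- getX(res, A)
  CX <- getC(res) %*% X

  # QR-based projector oracle
  Q <- qr.Q(qr(A[, cols@indices]))
  expect_equal(CX, Q %*% (t(Q) %*% A), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(res@relativeError,
               norm(A - Q %*% (t(Q) %*% A), "F") / norm(A, "F"),
               tolerance = 1e-8)
  # projection is idempotent
  expect_equal(getC(res) %*% (getU(res) %*% CX), CX, tolerance = 1e-8)
  # spanning selection reproduces A
  full <- buildRestricted(A, manualSelection(1:6, 6, "columns"),
                          leverageScores(A, 3), computeError = TRUE)
  expect_lt(full@relativeError, 1e-8)
})

test_that("approximation error has a hand-computable value on the identity", {
  A <- diag(4)
  res <- buildCUR(A, manualSelection(1, 4, "columns"),
                  manualSelection(1, 4, "rows"),
                  suppressWarnings(leverageScores(A, 1)))
  expect_equal(approximationError(A, res), sqrt(3) / 2, tolerance = 1e-10)
  expect_error(approximationError(matrix(0, 2, 2), res), "zero matrix")
})

test_that("CUR error respects the Eckart-Young lower bound", {
  for (seed in 1:5) {
    A <- seededMatrix(10, 8, seed + 20)
    d <- svd(A, nu = 0, nv = 0)$d
    res <- cur(A, c = 3, r = 3, k = 2, method = "top.scores",
               computeError = TRUE)
    s <- numericalRank(getC(res) %*% getU(res) %*% getR(res))
    best <- sqrt(sum(d[-seq_len(s)]^2)) / sqrt(sum(d^2))
    expect_gte(res@relativeError, best - 1e-8)
  }
})

test_that("cur resolves k by the 80% rule when omitted", {
  A <- diag(c(50, 30, 15, 5))
  res <- cur(A, c = 3, r = 3, method = "top.scores")
  expect_identical(res@k, 3L)
})

test_that("cur is bit-stable under a fixed seed and computes zero error on full rank", {
  A <- seededMatrix(7, 7, seed = 31)
  res <- cur(A, c = 7, r = 7, k = 2, method = "top.scores",
             computeError = TRUE)
  expect_lt(res@relativeError, 1e-8)

  r1 <- cur(A, c = 4, r = 4, k = 2, method = "random", seed = 5,
            computeError = TRUE)
  r2 <- cur(A, c = 4, r = 4, k = 2, method = "random", seed = 5,
            computeError = TRUE)
  expect_identical(r1@columnSelection@indices, r2@columnSelection@indices)
  expect_identical(r1@U, r2@U)
  expect_identical(r1@relativeError, r2@relativeError)
})

test_that("accessors guard mode mismatches and expose stored pieces", {
  A <- seededMatrix(6, 5, seed = 41)
  resF <- cur(A, c = 3, r = 3, k = 2, method = "top.scores")
  resR <- cur(A, c = 3, r = "all", k = 2, method = "top.scores")
  expect_error(getR(resR), "restricted")
  expect_error(getX(resF, A), "restricted")
  expect_null(relativeError(resF))
  expect_s4_class(resR, "CURDecomposition")

  # topLeverage agrees with selectTopScores on every count
  lev <- resF@leverage
  for (count in 1:5) {
    expect_identical(topLeverage(resF, count, "columns")$index,
                     selectTopScores(lev@columnScores, count)@indices)
  }
})

test_that("error modes propagate sensible messages", {
  A <- seededMatrix(5, 4, seed = 50)
  expect_error(cur(A, c = 2, r = 2, k = 9), "exceeds")
  empty <- manualSelection(integer(0), 4, "columns")
  expect_error(buildCUR(A, empty, manualSelection(1:2, 5, "rows"),
                        leverageScores(A, 2)), "empty")
})
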