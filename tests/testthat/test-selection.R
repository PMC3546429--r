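test_that("random selection honours degenerate probabilities and seeds", {
  sel <- selectRandom(c(1, 1, 0), seed = 99)
  expect_identical(sel@indices, c(1L, 2L))
  expect_identical(selectRandom(rep(0.5, 20), seed = 4),
                   selectRandom(rep(0.5, 20), seed = 4))
  expect_error(selectRandom(rep(0, 5)), "zero")
  expect_error(selectRandom(c(0.5, 1.5)), "\\[0, 1\\]")
})

test_that("random selection count follows the Bernoulli expectation", {
  p <- rep(0.5, 1000)
  one <- selectRandom(p, seed = 1)
  expect_lt(abs(length(one@indices) - 500), 3 * sqrt(1000 * 0.25))
  counts <- vapply(1:200, function(s)
    length(selectRandom(p, seed = s)@indices), numeric(1))
  expect_lt(abs(mean(counts) - 500) / 500, 0.02)
})

test_that("random selection count distribution is Bernoulli (chi-square)", {
  p <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  draws <- vapply(1:500, function(s)
    length(selectRandom(p, seed = 1000 + s)@indices), numeric(1))
  # oracle: distribution of a sum of independent Bernoullis, by
  # enumeration over the 2^10 outcomes
  outcomes <- as.matrix(expand.grid(rep(list(0:1), 10)))
  probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  sizeProb <- tapply(probs, rowSums(outcomes), sum)
  # condition on non-empty draws (the sampler redraws empty results)
  sizeProb <- sizeProb[names(sizeProb) != "0"]
  sizeProb <- sizeProb / sum(sizeProb)
  obs <- table(factor(draws, levels = names(sizeProb)))
  keep <- sizeProb * 500 >= 5  # pool sparse cells out of the test
  suppressWarnings(
    pval <- chisq.test(c(obs[keep], sum(obs[!keep])),
                       p = c(sizeProb[keep], sum(sizeProb[!keep])))$p.value)
  expect_gt(pval, 0.01)
})

test_that("exact-count selection returns the requested number", {
  scores <- c(0.4, 0.3, 0.2, 0.05, 0.05)
  for (s in 1:50) {
    sel <- selectExactNumRandom(scores, 3, seed = s)
    expect_length(sel@indices, 3)
    expect_false(anyDuplicated(sel@indices) > 0)
  }
  sel1 <- selectExactNumRandom(c(1, 0, 0, 0), 1, seed = 2)
  expect_identical(sel1@indices, 1L)
  expect_error(selectExactNumRandom(c(1, 0, 0), 2), "positive weights")
})

test_that("exact-count selection frequencies match the weights", {
  scores <- c(0.5, 0.3, 0.2)
  picks <- vapply(1:4000, function(s)
    selectExactNumRandom(scores, 1, seed = s)@indices, integer(1))
  freq <- tabulate(picks, 3) / 4000
  se <- sqrt(scores * (1 - scores) / 4000)
  expect_true(all(abs(freq - scores) < 3 * se))
})

test_that("top-score selection sorts descending with index tie-breaks", {
  expect_identical(selectTopScores(c(0.1, 0.4, 0.2, 0.3), 2)@indices,
                   c(2L, 4L))
  expect_identical(selectTopScores(c(0.3, 0.3, 0.4), 2)@indices,
                   c(3L, 1L))
  expect_identical(selectTopScores(c(0.2, 0.5, 0.3), 3)@indices,
                   c(2L, 3L, 1L))
})

test_that("ortho-top-score selection demotes duplicated columns", {
  # columns 1 and 2 identical; raw scores would pick both first
  A <- cbind(c(10, 0, 0, 0), c(10, 0, 0, 0), c(0, 5, 0, 0),
             c(0, 0, 2, 0))
  scores <- c(0.4, 0.4, 0.15, 0.05)
  sel <- selectOrthoTopScores(A, scores, 2)
  expect_identical(sel@indices[1], 1L)
  expect_false(2L %in% sel@indices)
  expect_identical(sel@indices[2], 3L)
})

test_that("ortho-top-score selection reduces to top scores on orthogonal data", {
  A <- diag(c(5, 4, 3, 2))
  scores <- c(0.1, 0.4, 0.3, 0.2)
  expect_identical(selectOrthoTopScores(A, scores, 4)@indices,
                   selectTopScores(scores, 4)@indices)
  expect_identical(selectOrthoTopScores(A, scores, 1)@indices,
                   selectTopScores(scores, 1)@indices)
})

test_that("ortho-top-score selection flags span exhaustion", {
  a1 <- c(1, 0, 0)
  a2 <- c(0, 1, 0)
  A <- cbind(a1, a2, a1 + a2, a1 - a2)  # rank 2
  scores <- c(0.4, 0.3, 0.2, 0.1)
  sel <- selectOrthoTopScores(A, scores, 4)
  expect_length(sel@indices, 4)
  expect_true(sel@spanFilled)
  # the fill is by raw score among the leftovers
  expect_identical(sel@indices[3:4], c(3L, 4L))
})

test_that("highest-rank selection enumerates rank parameters", {
  A <- diag(c(3, 2, 1))
  sel <- selectHighestRanks(A, k = 2, count = 2)
  expect_setequal(sel@indices, c(1L, 2L))

  # k = 1 reduces to top scores at rank 1
  B <- seededMatrix(10, 6, seed = 8)
  lev1 <- leverageScores(B, 1)
  expect_identical(selectHighestRanks(B, k = 1, count = 3)@indices,
                   selectTopScores(lev1@columnScores, 3)@indices)
})

test_that("highest-rank selections stay inside the union of per-rank tops", {
  for (seed in 1:5) {
    A <- seededMatrix(12, 9, seed)
    count <- 3
    k <- 4
    union <- integer(0)
    for (kp in 1:k) {
      lev <- leverageScores(A, kp)
      union <- base::union(union,
        selectTopScores(lev@columnScores, count)@indices)
    }
    sel <- selectHighestRanks(A, k = k, count = count)
    expect_true(all(sel@indices %in% union))
  }
})

test_that("the dispatcher routes methods and handles the 'all' sentinel", {
  A <- diag(c(3, 2, 1))
  lev <- leverageScores(A, 2)
  out <- selectFeatures(A, lev, "top.scores", c = 2, r = 2)
  expect_identical(out$columns@indices, c(1L, 2L))
  expect_identical(out$rows@indices, c(1L, 2L))

  res <- selectFeatures(A, lev, "top.scores", c = 2, r = "all")
  expect_null(res$rows)

  B <- seededMatrix(10, 8, seed = 6)
  levB <- leverageScores(B, 3)
  for (m in c("random", "exact.num.random")) {
    s1 <- selectFeatures(B, levB, m, c = 4, r = 4, seed = 11)
    s2 <- selectFeatures(B, levB, m, c = 4, r = 4, seed = 11)
    expect_identical(s1$columns@indices, s2$columns@indices)
    expect_identical(s1$rows@indices, s2$rows@indices)
  }
  expect_error(selectFeatures(B, levB, "not.a.method", c = 2, r = 2))
})

test_that("all strategies return distinct in-bounds indices", {
  A <- seededMatrix(15, 10, seed = 44)
  lev <- leverageScores(A, 3)
  for (m in c("random", "exact.num.random", "top.scores",
              "ortho.top.scores", "highest.ranks")) {
    out <- selectFeatures(A, lev, m, c = 5, r = 5, seed = 2)
    for (sel in list(out$columns, out$rows)) {
      expect_false(anyDuplicated(sel@indices) > 0)
      lim <- if (sel@axis == "columns") 10 else 15
      expect_true(all(sel@indices >= 1 & sel@indices <= lim))
    }
  }
})

test_that("a planted orthogonal column earns a top leverage score", {
  for (seed in 1:5) {
    k <- 3
    A <- exactRankMatrix(20, 12, s = k, seed = seed)
    set.seed(seed + 100)
    v <- rnorm(20)
    basis <- qr.Q(qr(A))[, 1:k]
    v <- v - basis %*% (t(basis) %*% v)
    v <- v / sqrt(sum(v^2)) * mean(sqrt(colSums(A^2)))
    Aplus <- cbind(A, planted = v)
    lev <- leverageScores(Aplus, k + 1)
    sel <- selectTopScores(lev@columnScores, k + 1)
    expect_true(13L %in% sel@indices)
  }
})
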