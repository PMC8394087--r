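test_that("cross-correlation matches a direct Pearson oracle", {
  A <- matrix(c(0, 2, 1, 3), 2, 2, byrow = TRUE)  # rows (0,1),(2,3)
  B <- matrix(c(1, 3, 0, 2), 2, 2, byrow = TRUE)
  # oracle: covariance formula on the flattened vectors
  av <- as.vector(A); bv <- as.vector(B)
  oracle <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(crossCorrelation(A, B), oracle)
  f <- testFrame(16)
  expect_equal(crossCorrelation(f, f), 1)
  expect_equal(crossCorrelation(f, max(f) - f), -1)
  expect_warning(v <- crossCorrelation(matrix(1, 4, 4), matrix(2, 4, 4)))
  expect_equal(v, 0)
  expect_error(crossCorrelation(matrix(0, 2, 2), matrix(0, 3, 3)), "dimensions")
})

test_that("frame dissimilarity is 1 - |CC| on [0, 1]", {
  f <- testFrame(16)
  expect_equal(frameDissimilarity(f, f), 0)
  expect_equal(frameDissimilarity(f, max(f) - f), 0)  # |CC| absorbs the sign
  set.seed(8)
  for (k in 1:10) {
    a <- matrix(rnorm(64), 8, 8); b <- matrix(rnorm(64), 8, 8)
    d <- frameDissimilarity(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, 1 - abs(cor(as.vector(a), as.vector(b))))
  }
})

test_that("cost matrix equals element-wise dissimilarities and is symmetric", {
  set.seed(9)
  fa <- replicate(2, matrix(runif(36, 0, 10), 6, 6), simplify = FALSE)
  fb <- replicate(3, matrix(runif(36, 0, 10), 6, 6), simplify = FALSE)
  pa <- pullback(fa); pb <- pullback(fb)
  d <- costMatrix(pa, pb)
  expect_equal(dim(d), c(2L, 3L))
  for (i in 1:2) for (j in 1:3)
    expect_equal(d[i, j], frameDissimilarity(fa[[i]], fb[[j]]))
  expect_equal(costMatrix(pb, pa), t(d))
  expect_equal(diag(costMatrix(pa, pa)), c(0, 0))
})

test_that("the accumulation recurrence reproduces hand-computed values", {
  costs <- matrix(c(0.1, 0.8, 0.9, 0.2), 2, 2)  # [[0.1,0.9],[0.8,0.2]]
  D0 <- dtwAccumulate(costs, dtwConfig(C = 0, openBoundaries = FALSE))
  expect_equal(D0, matrix(c(0.1, 0.9, 1.0, 0.3), 2, 2))
  D10 <- dtwAccumulate(costs, dtwConfig(C = 10, openBoundaries = FALSE))
  expect_equal(D10[2, 2], 0.3)          # diagonal predecessor already optimal
  expect_equal(D10[1, 2], 0.9 + 0.1 + 10)
  expect_equal(dtwAccumulate(matrix(0.4), dtwConfig(openBoundaries = FALSE)),
               matrix(0.4))
})

test_that("backtracked paths are optimal against exhaustive enumeration", {
  costs <- matrix(c(0.1, 0.8, 0.9, 0.2), 2, 2)
  cfg <- dtwConfig(C = 0, openBoundaries = FALSE)
  p <- dtwBacktrack(dtwAccumulate(costs, cfg), cfg)
  expect_equal(pathPairs(p), cbind(i = c(1L, 2L), j = c(1L, 2L)))
  set.seed(10)
  for (k in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    C <- sample(c(0, 0.05, 0.3), 1)
    costs <- matrix(runif(n * m), n, m)
    cfg <- dtwConfig(C = C, openBoundaries = FALSE)
    D <- dtwAccumulate(costs, cfg)
    path <- dtwBacktrack(D, cfg)
    expect_equal(pathCost(costs, path, C), D[n, m])
    expect_equal(D[n, m], bruteDtwMin(costs, C))
  }
})

test_that("ties break toward the diagonal and identity costs give the diagonal", {
  costs <- matrix(0.5, 4, 4)
  cfg <- dtwConfig(C = 0, openBoundaries = FALSE)
  p <- pathPairs(dtwBacktrack(dtwAccumulate(costs, cfg), cfg))
  expect_equal(p, cbind(i = 1:4, j = 1:4))
  zero <- diag(4) * 0  # identity pair: zero diagonal, positive elsewhere
  zero[zero == 0] <- 0.8; diag(zero) <- 0
  p2 <- pathPairs(dtwBacktrack(dtwAccumulate(zero, cfg), cfg))
  expect_equal(p2, cbind(i = 1:4, j = 1:4))
})

test_that("a larger regulariser never adds non-diagonal steps", {
  set.seed(12)
  nondiag <- function(path) {
    p <- pathPairs(path)
    if (nrow(p) < 2) return(0L)
    sum(rowSums(diff(p)) == 1L)
  }
  for (k in 1:10) {
    costs <- matrix(runif(49), 7, 7)
    counts <- vapply(c(0, 0.05, 0.2, 1), function(C) {
      cfg <- dtwConfig(C = C, openBoundaries = FALSE)
      nondiag(dtwBacktrack(dtwAccumulate(costs, cfg), cfg))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("self-registration yields the identity matching at zero cost", {
  pb <- generatePhantomPullback(8, c(48, 48), seed = 21)
  pp <- preprocessPullback(pb)
  for (C in c(0, 0.05, 0.5)) {
    res <- registerLongitudinal(pp, pp, dtwConfig(C = C))
    expect_equal(res$matches$index_a, 1:8)
    expect_equal(res$matches$index_b, 1:8)
    truth <- cbind(1:8, 1:8)
    expect_equal(alignmentError(truth, res$alignment@path), 0)
  }
})

test_that("a repeated frame produces a one-to-many match with zero error", {
  base <- generatePhantomPullback(10, c(48, 48), seed = 22)
  pb2 <- pullback(frames(base)[c(1, 2, 3, 3, 4:10)])
  pa <- preprocessPullback(base); pb <- preprocessPullback(pb2)
  res <- registerLongitudinal(pa, pb)
  p <- pathPairs(res$alignment@path)
  expect_true(all(c(3, 4) %in% p[p[, 1] == 3, 2]))
  truth <- cbind(c(1, 2, 3, 3, 4:10), seq_len(11))
  expect_equal(alignmentError(truth, res$alignment@path), 0)
})

test_that("open boundaries recover a central crop offset exactly", {
  base <- generatePhantomPullback(20, c(48, 48), seed = 23)
  crop <- pullback(frames(base)[4:17])
  pa <- preprocessPullback(base); pb <- preprocessPullback(crop)
  res <- registerLongitudinal(pa, pb, dtwConfig(openBoundaries = TRUE))
  p <- pathPairs(res$alignment@path)
  expect_equal(p[, 1], 4:17)
  expect_equal(p[, 2], 1:14)
})

test_that("accumulated costs are finite and non-decreasing along the path", {
  set.seed(24)
  costs <- matrix(runif(30), 5, 6)
  for (open in c(TRUE, FALSE)) {
    cfg <- dtwConfig(openBoundaries = open)
    D <- dtwAccumulate(costs, cfg)
    path <- pathPairs(dtwBacktrack(D, cfg))
    vals <- D[path]
    expect_true(all(is.finite(vals)))
    expect_true(all(diff(vals) >= -1e-12))
  }
})
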