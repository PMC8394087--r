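test_that("rigid resampling matches a pure-R per-pixel reference", {
  f <- testFrame(16)
  set.seed(31)
  for (k in 1:5) {
    tr <- rigidTransform(runif(1, -30, 30), runif(1, -4, 4), runif(1, -4, 4))
    expect_equal(applyRigid(f, tr),
                 applyRigidR(f, tr@angle, tr@tx, tr@ty), tolerance = 1e-12)
  }
})

test_that("identity and full-turn transforms reproduce the input", {
  f <- testFrame(32)
  expect_identical(applyRigid(f, rigidTransform(0, 0, 0)), f)
  turned <- applyRigid(f, rigidTransform(360, 0, 0))
  interior <- 8:24
  expect_equal(turned[interior, interior], f[interior, interior],
               tolerance = 1e-6)
})

test_that("a transform followed by its inverse recovers interior pixels", {
  f <- testFrame(48)
  set.seed(32)
  for (k in 1:4) {
    tr <- rigidTransform(runif(1, -15, 15), runif(1, -5, 5), runif(1, -5, 5))
    back <- applyRigid(applyRigid(f, tr), rigidInverse(tr))
    interior <- 16:32
    expect_lt(max(abs(back[interior, interior] - f[interior, interior])), 6)
    # algebra check via the coordinate-mapping oracle: forward then inverse
    # maps any point to itself
    p <- c(runif(1, 0, 47), runif(1, 0, 47))
    inv <- rigidInverse(tr)
    q <- fwdPoint(fwdPoint(p, tr@angle, tr@tx, tr@ty, 48, 48),
                  inv@angle, inv@tx, inv@ty, 48, 48)
    expect_equal(q, p, tolerance = 1e-10)
  }
})

test_that("rigid composition matches sequential coordinate mapping", {
  set.seed(33)
  for (k in 1:5) {
    a <- rigidTransform(runif(1, -40, 40), runif(1, -6, 6), runif(1, -6, 6))
    b <- rigidTransform(runif(1, -40, 40), runif(1, -6, 6), runif(1, -6, 6))
    ab <- rigidCompose(a, b)
    p <- c(runif(1, 0, 63), runif(1, 0, 63))
    seq2 <- fwdPoint(fwdPoint(p, b@angle, b@tx, b@ty, 64, 64),
                     a@angle, a@tx, a@ty, 64, 64)
    expect_equal(fwdPoint(p, ab@angle, ab@tx, ab@ty, 64, 64), seq2,
                 tolerance = 1e-10)
  }
})

test_that("mutual information reproduces the hand-built joint histogram case", {
  # half the pixels in bin 1 paired with bin 1, half in bin 2 with bin 2:
  # joint mass [[0.5, 0], [0, 0.5]] -> MI = ln 2 by the four-term sum
  img <- matrix(c(rep(0, 8), rep(10, 8)), 4, 4)
  expect_equal(mutualInformation(img, img, miConfig(nBins = 2)), log(2))
  # direct evaluation of the double sum as an independent check
  pj <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  direct <- sum(ifelse(pj > 0, pj * log(pj / (rowSums(pj) %o% colSums(pj))), 0))
  expect_equal(direct, log(2))
})

test_that("MI is symmetric, non-negative, zero against constants, and equals
           the marginal entropy on identical images", {
  set.seed(34)
  for (k in 1:5) {
    a <- matrix(runif(256, 0, 100), 16, 16)
    b <- matrix(runif(256, 0, 100), 16, 16)
    cfg <- miConfig(nBins = 8, range = c(0, 100))
    expect_equal(mutualInformation(a, b, cfg), mutualInformation(b, a, cfg))
    expect_gte(mutualInformation(a, b, cfg), 0)
    # entropy of the binned marginal
    counts <- tabulate(pmin(floor(a / 12.5) + 1, 8), 8)
    p <- counts / sum(counts)
    expect_equal(mutualInformation(a, a, cfg), -sum(p[p > 0] * log(p[p > 0])))
  }
  expect_equal(mutualInformation(testFrame(16), matrix(5, 16, 16)), 0)
  expect_error(mutualInformation(matrix(0, 2, 2), matrix(0, 3, 3)), "dimensions")
})

test_that("harmony construction honours the degenerate branch probabilities", {
  # memory of one solution, h = 1, p = 0: the candidate must equal it exactly
  cfg <- harmonyConfig(memorySize = 1L, hInit = 1, hMax = 1, pInit = 0,
                       pMax = 0, maxIterations = 5L,
                       bounds = rbind(c(-5, 5), c(-5, 5)), seed = 3L)
  seen <- new.env(); seen$x <- list()
  obj <- function(x) { seen$x <- c(seen$x, list(x)); -sum((x - 1)^2) }
  st <- harmonySearch(obj, cfg, seedSolutions = list(c(1, 1)))
  for (cand in seen$x[-1]) expect_equal(cand, c(1, 1))
  # degenerate bounds pin every candidate to the single feasible point
  cfg2 <- harmonyConfig(memorySize = 3L, hInit = 0, hMax = 0,
                        maxIterations = 5L,
                        bounds = rbind(c(2, 2), c(-1, -1)), seed = 4L)
  st2 <- harmonySearch(function(x) -sum(x^2), cfg2)
  expect_equal(st2$best$solution, c(2, -1))
})

test_that("harmony search finds a 1-D optimum to grid-search accuracy", {
  obj <- function(x) -(x - 3)^2
  cfg <- harmonyConfig(memorySize = 10L, maxIterations = 200L,
                       bounds = rbind(c(0, 10)), seed = 7L)
  st <- harmonySearch(obj, cfg)
  grid <- seq(0, 10, by = 0.001)
  best <- grid[which.max(obj(grid))]
  expect_lt(abs(st$best$solution - best), 0.1)
})

test_that("the ALOPEX step is sign-biased toward recent improvement", {
  bounds <- rbind(c(-10, 10), c(-10, 10))
  history <- list(list(solution = c(1, -1), value = 2),
                  list(solution = c(0, 0), value = 1))  # dx=(1,-1), dJ=1
  set.seed(35)
  draws <- replicate(1e4, alopexPerturbation(history, 1, bounds))
  expect_gt(mean(draws[1, ] > 0), 0.5)   # dx*dJ > 0: push further
  expect_gt(mean(draws[2, ] < 0), 0.5)   # dx*dJ < 0 in dim 2
  # temperature scales the magnitude toward zero
  tiny <- replicate(100, alopexPerturbation(history, 1e-9, bounds))
  expect_lt(max(abs(tiny)), 1e-6)
  # no history: uniform fallback within +/-1% of the bound range
  set.seed(36)
  fb <- replicate(500, alopexPerturbation(list(), 1, bounds))
  expect_lte(max(abs(fb)), 0.01 * 20)
  expect_gt(max(abs(fb)), 0.001)
})

test_that("self-registration stays at the identity transform", {
  f <- preprocessPullback(generatePhantomPullback(1, c(64, 64), seed = 41),
                          normalize = FALSE)
  frame <- getFrame(f, 1)
  res <- registerAxialPair(frame, frame, hsCfg = harmonyConfig(seed = 11L))
  pars <- transformParams(res$transform)
  expect_lt(abs(pars["angle"]), 0.5)
  expect_lt(abs(pars["tx"]), 0.5)
  expect_lt(abs(pars["ty"]), 0.5)
  expect_gte(res$miAfter, res$miBefore - 1e-9)  # monotone-best memory
})

test_that("a known rigid perturbation is recovered to grid-search accuracy", {
  base <- generatePhantomPullback(1, c(64, 64), seed = 42)
  ref <- getFrame(preprocessPullback(base), 1)
  t0 <- rigidTransform(10, 3, -2)
  floating <- applyRigid(ref, t0)
  res <- registerAxialPair(floating, ref, hsCfg = harmonyConfig(seed = 13L))
  grid <- gridBestRigid(floating, ref)
  # the optimum neutralises the applied perturbation
  inv <- rigidInverse(t0)
  expect_lt(abs(res$transform@angle - inv@angle), 1)
  expect_lt(sqrt((res$transform@tx - inv@tx)^2 + (res$transform@ty - inv@ty)^2), 1)
  # and agrees with the exhaustive grid search
  expect_lt(abs(res$transform@angle - grid$par[1]), 1)
  expect_lt(sqrt(sum((c(res$transform@tx, res$transform@ty) -
                        grid$par[2:3])^2)), 1)
  expect_gte(res$miAfter, grid$value - 0.05)
})

test_that("bounds degenerate at the identity return the identity", {
  f <- testFrame(32)
  cfg <- harmonyConfig(bounds = rbind(c(0, 0), c(0, 0), c(0, 0)),
                       maxIterations = 20L, seed = 5L)
  res <- registerAxialPair(f, f, hsCfg = cfg)
  expect_equal(transformParams(res$transform),
               c(angle = 0, tx = 0, ty = 0))
})

test_that("axial registration is deterministic and order-independent", {
  pa <- preprocessPullback(generatePhantomPullback(3, c(48, 48), seed = 44))
  pb <- pa
  matches <- data.frame(index_a = c(1L, 2L, 3L), index_b = c(1L, 2L, 3L),
                        dissimilarity = 0)
  cfg <- harmonyConfig(maxIterations = 50L, seed = 99L)
  r1 <- registerAxial(matches, pa, pb, hsCfg = cfg)
  r2 <- registerAxial(matches[c(3, 1, 2), ], pa, pb, hsCfg = cfg)
  ord <- order(r2$matches$index_a)
  expect_equal(r2$matches$angle_deg[ord], r1$matches$angle_deg)
  expect_equal(r2$matches$mi_after[ord], r1$matches$mi_after)
  r3 <- registerAxial(matches, pa, pb, hsCfg = cfg)
  expect_identical(r1$matches, r3$matches)
  empty <- registerAxial(matches[0, ], pa, pb, hsCfg = cfg)
  expect_equal(nrow(empty$matches), 0L)
  expect_equal(length(empty$transforms), 0L)
})
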