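# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force so they share no code with the implementation.

# Minimum total cost over all monotone paths from (1,1) to (n,m) with steps
# (1,0), (0,1), (1,1), charging d at every visited cell and +C per
# non-diagonal step: exhaustive recursion, feasible up to ~6x6.
bruteDtwMin <- function(costs, C) {
  n <- nrow(costs); m <- ncol(costs)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(costs[1, 1])
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j) + C)
    if (j > 1) best <- min(best, rec(i, j - 1) + C)
    costs[i, j] + best
  }
  rec(n, m)
}

# Total cost of a concrete warping path under the same penalty scheme.
pathCost <- function(costs, path, C) {
  p <- pathPairs(path)
  steps <- diff(p)
  nondiag <- if (nrow(p) > 1) sum(rowSums(steps) == 1L) else 0L
  sum(costs[p]) + C * nondiag
}

# Dense grid search over rigid transforms, maximising the same binned MI;
# the optimiser under test never sees this.
gridBestRigid <- function(floating, reference, nBins = 32L,
                          angles = seq(-20, 20, by = 0.5),
                          shifts = seq(-8, 8, by = 0.5)) {
  rng <- range(floating, reference)
  best <- c(NA, NA, NA); bestV <- -Inf
  for (a in angles) for (tx in shifts) for (ty in shifts) {
    v <- ivusreg:::cpp_rigid_mi(floating, reference, a, tx, ty, nBins,
                                rng[1], rng[2])
    if (v > bestV) { bestV <- v; best <- c(a, tx, ty) }
  }
  list(par = best, value = bestV)
}

# Pure-R forward rigid mapping of a point (x, y) (column, row, 0-based):
# rotate counter-clockwise about the frame centre, then translate.
fwdPoint <- function(xy, angle, tx, ty, H, W) {
  th <- angle * pi / 180
  c0 <- c((W - 1) / 2, (H - 1) / 2)
  d <- xy - c0
  c(cos(th) * d[1] - sin(th) * d[2], sin(th) * d[1] + cos(th) * d[2]) +
    c0 + c(tx, ty)
}

# Pure-R reference implementation of the inverse-mapped bilinear resampler,
# written with explicit per-pixel loops.
applyRigidR <- function(img, angle, tx, ty) {
  H <- nrow(img); W <- ncol(img)
  th <- angle * pi / 180
  out <- matrix(0, H, W)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  for (r in seq_len(H)) for (c in seq_len(W)) {
    dx <- (c - 1) - cx - tx
    dy <- (r - 1) - cy - ty
    sx <- cos(th) * dx + sin(th) * dy + cx
    sy <- -sin(th) * dx + cos(th) * dy + cy
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    v <- 0
    for (dy2 in 0:1) for (dx2 in 0:1) {
      xx <- x0 + dx2; yy <- y0 + dy2
      if (xx >= 0 && xx < W && yy >= 0 && yy < H) {
        w <- (if (dx2 == 1) fx else 1 - fx) * (if (dy2 == 1) fy else 1 - fy)
        v <- v + w * img[yy + 1, xx + 1]
      }
    }
    out[r, c] <- v
  }
  out
}

# Small structured test frame: off-centre blob plus gradient, non-constant
# and asymmetric so correlations and MI are informative.
testFrame <- function(n = 32, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    x <- matrix(rep(seq_len(n), each = n), n, n)
    y <- matrix(rep(seq_len(n), n), n, n)
    100 * exp(-((x - n / 3)^2 + (y - n / 2)^2) / (n / 2)^2) +
      0.5 * x + matrix(runif(n * n, 0, 10), n, n)
  })
}
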