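#' Harmony Search configuration
#'
#' Parameters of the Harmony Search variant used to maximise mutual
#' information over rigid transforms. New candidates are assembled
#' element-wise from the memory of previous solutions, from memory elements
#' nudged by an ALOPEX-style tuning step, or from uniform draws over the
#' search bounds; the memory-consideration rate h and pitch-adjustment rate p
#' both increase linearly over the run, shifting from exploration to
#' exploitation.
#'
#' @param memorySize number of solutions kept in memory; default 20.
#' @param hInit,hMax memory-consideration probability schedule endpoints,
#'   default 0.7 to 0.95.
#' @param pInit,pMax pitch-adjustment probability schedule endpoints, default
#'   0.1 to 0.5.
#' @param maxIterations number of candidate constructions; default 500.
#' @param bounds d x 2 matrix of (min, max) per solution dimension; default
#'   the rigid-registration space angle in [-20, 20] degrees and translation
#'   in [-8, 8] pixels -- slightly wider than the simulator's perturbation
#'   ranges so true optima never sit on the boundary.
#' @param stepScale ALOPEX step magnitude as a fraction of each bound range
#'   at temperature 1; default 0.05.
#' @param temperatureDecay geometric cooling factor per iteration; default 0.99.
#' @param seed integer RNG seed for the run.
#' @return a named list of validated parameters.
#' @export
harmonyConfig <- function(memorySize = 20L, hInit = 0.7, hMax = 0.95,
                          pInit = 0.1, pMax = 0.5, maxIterations = 500L,
                          bounds = rbind(angle = c(-20, 20),
                                         tx = c(-8, 8), ty = c(-8, 8)),
                          stepScale = 0.05, temperatureDecay = 0.99,
                          seed = 1L) {
  if (memorySize < 1) stop("'memorySize' must be positive", call. = FALSE)
  probs <- c(hInit, hMax, pInit, pMax)
  if (any(probs < 0 | probs > 1))
    stop("h and p must be probabilities in [0, 1]", call. = FALSE)
  if (hInit > hMax || pInit > pMax)
    stop("schedules must be non-decreasing (init <= max)", call. = FALSE)
  if (maxIterations < 1) stop("'maxIterations' must be positive", call. = FALSE)
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(bounds[, 2] < bounds[, 1]))
    stop("'bounds' must be a d x 2 matrix with min <= max", call. = FALSE)
  list(memorySize = as.integer(memorySize), hInit = hInit, hMax = hMax,
       pInit = pInit, pMax = pMax, maxIterations = as.integer(maxIterations),
       bounds = bounds, stepScale = stepScale,
       temperatureDecay = temperatureDecay, seed = as.integer(seed))
}

#' ALOPEX-style tuning step
#'
#' Produces the per-dimension tuning step e used by the pitch-adjustment
#' branch. The step's sign is biased (probability 0.75) toward the direction
#' of the most recent objective improvement -- the sign of
#' \code{(delta x_i) * (delta J)} between the last two evaluated solutions, as
#' in correlation-based ALOPEX updates -- and its magnitude is drawn as
#' |N(0, 1)| scaled by the annealing temperature and the bound range, so the
#' step shrinks as the run cools. With fewer than two evaluations on record
#' it falls back to a uniform draw within +/-1% of each bound range.
#'
#' @param history list of up to two \code{list(solution, value)} entries,
#'   most recent first.
#' @param temperature positive annealing temperature.
#' @param bounds d x 2 bounds matrix (sets the step scale per dimension).
#' @param stepScale magnitude scale as a fraction of the bound range.
#' @return numeric step vector of length d (uses the current RNG stream).
#' @export
alopexPerturbation <- function(history, temperature, bounds, stepScale = 0.05) {
  d <- nrow(bounds)
  rng <- bounds[, 2] - bounds[, 1]
  if (length(history) < 2L)
    return(stats::runif(d, -0.01, 0.01) * rng)
  dx <- history[[1]]$solution - history[[2]]$solution
  dJ <- history[[1]]$value - history[[2]]$value
  sgn <- sign(dx * dJ)
  undecided <- sgn == 0
  sgn[undecided] <- sample(c(-1, 1), sum(undecided), replace = TRUE)
  flip <- stats::runif(d) >= 0.75
  sgn[flip] <- -sgn[flip]
  sgn * abs(stats::rnorm(d)) * temperature * stepScale * rng
}

harmonyInit <- function(config, objective, seedSolutions = list()) {
  d <- nrow(config$bounds)
  mem <- matrix(stats::runif(config$memorySize * d,
                             rep(config$bounds[, 1], each = config$memorySize),
                             rep(config$bounds[, 2], each = config$memorySize)),
                config$memorySize, d)
  for (k in seq_along(seedSolutions))
    if (k <= config$memorySize)
      mem[k, ] <- pmin(pmax(seedSolutions[[k]], config$bounds[, 1]),
                       config$bounds[, 2])
  vals <- apply(mem, 1, objective)
  ord <- order(vals, decreasing = TRUE)
  mem <- mem[ord, , drop = FALSE]; vals <- vals[ord]
  list(memory = mem, values = vals, iteration = 0L,
       best = list(solution = mem[1, ], value = vals[1]),
       history = list(), temperature = 1)
}

#' One Harmony Search iteration
#'
#' Builds one candidate element-wise: with probability \code{h (1 - p)} the
#' element is copied from a uniformly chosen memory solution, with
#' probability \code{h p} it is copied and perturbed by the ALOPEX step, and
#' with probability \code{1 - h} it is drawn uniformly from the bounds. The
#' candidate (clamped to the bounds) replaces the worst memory entry if it
#' scores better; h and p advance along their linear schedules and the
#' annealing temperature decays geometrically. Maximisation throughout.
#'
#' @param state state list from \code{harmonyInit} or a previous step.
#' @param config a [harmonyConfig()] list.
#' @param objective function from solution vector to finite scalar
#'   (candidates with non-finite objectives are rejected with a warning).
#' @return the updated state.
#' @export
harmonyStep <- function(state, config, objective) {
  d <- nrow(config$bounds)
  frac <- state$iteration / config$maxIterations
  h <- config$hInit + (config$hMax - config$hInit) * min(frac, 1)
  p <- config$pInit + (config$pMax - config$pInit) * min(frac, 1)
  e <- alopexPerturbation(state$history, state$temperature, config$bounds,
                          config$stepScale)
  u <- stats::runif(d)
  k <- sample.int(nrow(state$memory), d, replace = TRUE)
  cand <- numeric(d)
  for (i in seq_len(d)) {
    cand[i] <- if (u[i] < h * (1 - p)) {
      state$memory[k[i], i]
    } else if (u[i] < h) {
      state$memory[k[i], i] + e[i]
    } else {
      stats::runif(1, config$bounds[i, 1], config$bounds[i, 2])
    }
  }
  cand <- pmin(pmax(cand, config$bounds[, 1]), config$bounds[, 2])
  val <- objective(cand)
  if (is.finite(val)) {
    worst <- length(state$values)
    if (val > state$values[worst]) {
      state$memory[worst, ] <- cand
      state$values[worst] <- val
      ord <- order(state$values, decreasing = TRUE)
      state$memory <- state$memory[ord, , drop = FALSE]
      state$values <- state$values[ord]
    }
    if (val > state$best$value)
      state$best <- list(solution = cand, value = val)
    state$history <- c(list(list(solution = cand, value = val)),
                       state$history)[seq_len(min(2L, length(state$history) + 1L))]
  } else {
    warning("objective returned a non-finite value; candidate rejected")
  }
  state$iteration <- state$iteration + 1L
  state$temperature <- state$temperature * config$temperatureDecay
  state
}

#' Run Harmony Search to maximise an objective
#'
#' Initialises the memory from uniform draws (plus any seeded solutions) and
#' iterates [harmonyStep()] for \code{maxIterations} constructions under the
#' configured RNG seed.
#'
#' @param objective function from solution vector to scalar (maximised).
#' @param config a [harmonyConfig()] list.
#' @param seedSolutions list of solution vectors to place in the initial
#'   memory (e.g. the identity transform).
#' @return final state; \code{$best$solution} and \code{$best$value} hold the
#'   optimum found.
#' @export
harmonySearch <- function(objective, config = harmonyConfig(),
                          seedSolutions = list()) {
  withSeed(config$seed, {
    state <- harmonyInit(config, objective, seedSolutions)
    for (it in seq_len(config$maxIterations))
      state <- harmonyStep(state, config, objective)
    state
  })
}

#' Rigid registration of one frame pair by Harmony Search over MI
#'
#' Searches the 3-dimensional space (angle, tx, ty) for the rigid transform
#' of the floating frame that maximises its mutual information with the
#' reference frame. The identity transform is always seeded into the initial
#' memory, so the returned transform never scores below the identity.
#'
#' @param floating,reference numeric matrices of identical dimension
#'   (preprocessed frames).
#' @param miCfg a [miConfig()] list.
#' @param hsCfg a [harmonyConfig()] list (its \code{seed} fixes the run).
#' @return list with \code{transform} ([RigidTransform-class]),
#'   \code{miBefore} (MI at identity) and \code{miAfter} (MI at the optimum).
#' @export
registerAxialPair <- function(floating, reference, miCfg = miConfig(),
                              hsCfg = harmonyConfig()) {
  if (!identical(dim(floating), dim(reference)))
    stop("frames must have identical dimensions", call. = FALSE)
  rng <- miRange(floating, reference, miCfg)
  objective <- function(x)
    cpp_rigid_mi(floating, reference, x[1], x[2], x[3], miCfg$nBins,
                 rng[1], rng[2])
  state <- harmonySearch(objective, hsCfg, seedSolutions = list(c(0, 0, 0)))
  best <- state$best
  list(transform = rigidTransform(best$solution[1], best$solution[2],
                                  best$solution[3]),
       miBefore = mutualInformation(floating, reference,
                                    miConfig(miCfg$nBins, rng)),
       miAfter = best$value)
}

#' Axial registration of all matched frame pairs
#'
#' Runs [registerAxialPair()] for every row of a longitudinal match table,
#' with the floating frame taken from pullback B and the reference from
#' pullback A. Each pair gets its own RNG stream derived deterministically
#' from \code{(globalSeed, index_a, index_b)}, so results are identical
#' whatever the processing order.
#'
#' @param matches data frame from [registerLongitudinal()] (may be empty).
#' @param pa,pb the preprocessed [Pullback-class] pair.
#' @param miCfg a [miConfig()] list.
#' @param hsCfg a [harmonyConfig()] list; its seed acts as the global seed.
#' @return list with \code{matches} (the table enriched with
#'   \code{angle_deg, tx_px, ty_px, mi_before, mi_after}) and
#'   \code{transforms}, a list of [RigidTransform-class] per row.
#' @export
registerAxial <- function(matches, pa, pb, miCfg = miConfig(),
                          hsCfg = harmonyConfig()) {
  n <- nrow(matches)
  out <- matches
  out$angle_deg <- numeric(n); out$tx_px <- numeric(n); out$ty_px <- numeric(n)
  out$mi_before <- numeric(n); out$mi_after <- numeric(n)
  transforms <- vector("list", n)
  for (r in seq_len(n)) {
    ia <- matches$index_a[r]; ib <- matches$index_b[r]
    cfg <- hsCfg
    cfg$seed <- pairSeed(hsCfg$seed, ia, ib)
    res <- registerAxialPair(getFrame(pb, ib), getFrame(pa, ia), miCfg, cfg)
    transforms[[r]] <- res$transform
    out$angle_deg[r] <- res$transform@angle
    out$tx_px[r] <- res$transform@tx
    out$ty_px[r] <- res$transform@ty
    out$mi_before[r] <- res$miBefore
    out$mi_after[r] <- res$miAfter
  }
  list(matches = out, transforms = transforms)
}
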