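## Linear structural-equation simulator emulating a gene-knockout study:
## observational equilibrium samples, hard-clamp interventions, and direct /
## ancestral ground truth. This is the package's testing device; it makes no
## claim about any particular biological data-generating process.

#' Sample a random linear structural-equation system
#'
#' Nonzero direct effects are drawn with magnitude uniform in [0.5, 1.5] and
#' random sign. Acyclic systems restrict the support to a random topological
#' order (B is permutation-similar to strictly triangular); cyclic systems
#' allow any off-diagonal support and are rescaled, if necessary, to
#' spectral radius 0.9 so the equilibrium exists.
#'
#' @param p integer >= 2, number of variables.
#' @param edgeDensity probability of each admissible direct edge, in (0, 1).
#' @param cyclic logical, permit cycles (default \code{FALSE}).
#' @param noiseScale positive noise standard deviations, recycled to length
#'   p (default 1).
#' @param seed integer seed.
#' @return A [SEMSpec-class].
#' @examples
#' spec <- sampleSEMSpec(10, 0.1, seed = 1)
#' sum(semWeights(spec) != 0)
#' @export
sampleSEMSpec <- function(p, edgeDensity, cyclic = FALSE, noiseScale = 1,
                          seed = 1L) {
  p <- as.integer(p)
  if (p < 2) stop("p must be at least 2")
  if (edgeDensity <= 0 || edgeDensity >= 1)
    stop("edgeDensity must lie strictly in (0, 1)")
  B <- withSeed(seed, {
    B <- matrix(0, p, p)
    if (cyclic) {
      support <- matrix(stats::runif(p * p) < edgeDensity, p, p)
      diag(support) <- FALSE
    } else {
      ord <- sample.int(p)
      support <- matrix(FALSE, p, p)
      for (a in seq_len(p - 1)) for (b in (a + 1):p)
        support[ord[a], ord[b]] <- stats::runif(1) < edgeDensity
    }
    ne <- sum(support)
    B[support] <- sample(c(-1, 1), ne, replace = TRUE) *
      stats::runif(ne, 0.5, 1.5)
    if (cyclic) {
      rho <- max(Mod(eigen(B, only.values = TRUE)$values))
      if (rho > 0.9) B <- B * (0.9 / rho)
    }
    B
  })
  new("SEMSpec", B = B, noiseScale = rep(as.numeric(noiseScale), length.out = p),
      cyclic = isTRUE(cyclic), seed = as.integer(seed))
}

#' Simulate observational equilibrium samples
#'
#' Each sample solves \code{z = B'z + e} at equilibrium, i.e.
#' \code{z = (I - B')^{-1} e} with independent Gaussian noise \code{e}.
#'
#' @param spec [SEMSpec-class] (stable).
#' @param n number of samples.
#' @param seed integer seed.
#' @return numeric n x p matrix with variable names \code{V1..Vp}.
#' @examples
#' spec <- sampleSEMSpec(5, 0.2, seed = 1)
#' dim(simulateObservational(spec, 100, seed = 2))
#' @export
simulateObservational <- function(spec, n, seed = 1L) {
  stopifnot(is(spec, "SEMSpec"))
  validObject(spec)
  p <- nrow(spec@B)
  E <- withSeed(seed,
    matrix(stats::rnorm(n * p), n, p) %*% diag(spec@noiseScale, p))
  Z <- E %*% solve(diag(p) - spec@B)
  colnames(Z) <- paste0("V", seq_len(p))
  Z
}

#' Simulate samples under a hard intervention
#'
#' Clamps the target variable to \code{clampValue} (graph surgery: the
#' target's structural equation is replaced by the constant) and solves the
#' reduced equilibrium for the remaining variables. The default clamp of
#' -20 on the standardized scale models a hard knockout: the intervened
#' variable is forced far outside its observational range, as a gene
#' deletion is on an expression scale.
#'
#' @param spec [SEMSpec-class].
#' @param target variable index to clamp.
#' @param n number of samples.
#' @param clampValue value the target is clamped to (default -20).
#' @param seed integer seed.
#' @return numeric n x p matrix; the target column is constant. The target
#'   index is attached as attribute \code{"target"}.
#' @examples
#' spec <- sampleSEMSpec(5, 0.2, seed = 1)
#' zi <- simulateIntervention(spec, target = 2, n = 10, seed = 3)
#' var(zi[, 2])   # 0: clamped
#' @export
simulateIntervention <- function(spec, target, n, clampValue = -20,
                                 seed = 1L) {
  stopifnot(is(spec, "SEMSpec"))
  p <- nrow(spec@B)
  target <- as.integer(target)
  if (is.na(target) || target < 1 || target > p)
    stop("target out of range")
  Bm <- spec@B[-target, -target, drop = FALSE]
  bt <- spec@B[target, -target]
  E <- withSeed(seed, matrix(stats::rnorm(n * (p - 1)), n, p - 1) %*%
                  diag(spec@noiseScale[-target], p - 1))
  Zm <- sweep(E, 2, clampValue * bt, `+`) %*% solve(diag(p - 1) - Bm)
  Z <- matrix(clampValue, n, p)
  Z[, -target] <- Zm
  colnames(Z) <- paste0("V", seq_len(p))
  attr(Z, "target") <- target
  Z
}

#' Single-replicate knockout panel
#'
#' Runs one hard-clamp intervention per variable and records one
#' measurement of every variable per experiment, emulating a gene-deletion
#' compendium: row i of the result is the measurement vector under the
#' knockout of variable i (input format of [goldStandard()]).
#'
#' @param spec [SEMSpec-class].
#' @param clampValue clamp value (default -20).
#' @param seed integer seed.
#' @return numeric p x p matrix.
#' @examples
#' spec <- sampleSEMSpec(5, 0.2, seed = 1)
#' dim(interventionPanel(spec, seed = 4))
#' @export
interventionPanel <- function(spec, clampValue = -20, seed = 1L) {
  stopifnot(is(spec, "SEMSpec"))
  p <- nrow(spec@B)
  Z <- matrix(0, p, p)
  for (t in seq_len(p))
    Z[t, ] <- simulateIntervention(spec, t, n = 1, clampValue = clampValue,
                                   seed = subSeed(seed, t))
  dimnames(Z) <- list(paste0("V", 1:p), paste0("V", 1:p))
  Z
}

#' Direct and ancestral ground truth of a system
#'
#' Direct truth marks the nonzero entries of B. Ancestral truth thresholds
#' the total-effect matrix \code{T = (I - B)^{-1} - I} at
#' \code{effectThreshold} (total effects of negligible magnitude are not
#' scientifically relevant edges) and always contains the direct edges.
#'
#' @param spec [SEMSpec-class].
#' @param effectThreshold minimum |total effect| for an ancestral edge
#'   (default 0.1).
#' @return list with binary matrices \code{direct} and \code{ancestral}
#'   and the total-effect matrix \code{total}.
#' @examples
#' spec <- sampleSEMSpec(5, 0.2, seed = 1)
#' str(groundTruth(spec))
#' @export
groundTruth <- function(spec, effectThreshold = 0.1) {
  stopifnot(is(spec, "SEMSpec"))
  p <- nrow(spec@B)
  direct <- (spec@B != 0) * 1L
  total <- solve(diag(p) - spec@B) - diag(p)
  ancestral <- ((abs(total) > effectThreshold) | direct > 0) * 1L
  diag(ancestral) <- 0L
  list(direct = direct, ancestral = ancestral, total = total)
}

#' Simulate a complete synthetic knockout study
#'
#' Bundles a sampled system with observational samples, the
#' single-replicate knockout panel, and both ground truths.
#'
#' @param p,edgeDensity,cyclic,noiseScale,seed passed to [sampleSEMSpec()].
#' @param nObs observational sample count (default 1000; half feeds the
#'   gold-standard medians/IQRs, half is training data).
#' @param clampValue knockout clamp (default -20).
#' @param effectThreshold ancestral relevance threshold (default 0.1).
#' @return A [SyntheticSystem-class].
#' @examples
#' sys <- simulateSystem(p = 6, edgeDensity = 0.2, nObs = 100, seed = 1)
#' sys
#' @export
simulateSystem <- function(p = 20, edgeDensity = 0.1, nObs = 1000,
                           cyclic = FALSE, noiseScale = 1,
                           clampValue = -20, effectThreshold = 0.1,
                           seed = 1L) {
  spec <- sampleSEMSpec(p, edgeDensity, cyclic, noiseScale,
                        seed = subSeed(seed, 1))
  obs <- simulateObservational(spec, nObs, seed = subSeed(seed, 2))
  panel <- interventionPanel(spec, clampValue, seed = subSeed(seed, 3))
  tr <- groundTruth(spec, effectThreshold)
  new("SyntheticSystem", spec = spec, observational = obs,
      interventionPanel = panel, clampValue = clampValue,
      truthDirect = tr$direct, truthAncestral = tr$ancestral)
}

#' Synthetic end-to-end recovery benchmark
#'
#' For each seed: draw systems until the gold standard derived from the
#' simulated knockout panel passes the sparsity screens, sample training
#' labels from the gold-standard adjacency (row-wise or random design), run
#' the full estimator on the reserved observational training half, and
#' score the unlabelled pairs against the held-out adjacency entries by
#' AUC. With \code{permuteLabels} the training labels are randomly permuted
#' before fitting, giving the chance-level reference of the same pipeline.
#'
#' @param nSeeds number of replicate studies (default 10).
#' @param p,edgeDensity,nObs,clampValue passed to [simulateSystem()].
#' @param rho label fraction (default 0.3).
#' @param design \code{"rowwise"} (default) or \code{"random"}.
#' @param tau gold-standard threshold (default 5).
#' @param config [mrclConfig()] overrides for the estimator.
#' @param permuteLabels logical; permute training labels (null reference).
#' @param maxTries systems tried per seed before giving up the screens.
#' @param seed master seed.
#' @return data.frame with one row per seed: \code{auc}, \code{nEdges}
#'   (gold-standard edges), \code{mL} (labels used), \code{nTest}.
#' @examples
#' \donttest{
#' syntheticBenchmark(nSeeds = 2, p = 10, nObs = 200, seed = 1)
#' }
#' @export
syntheticBenchmark <- function(nSeeds = 10, p = 20, edgeDensity = 0.1,
                               nObs = 1000, rho = 0.3,
                               design = c("rowwise", "random"), tau = 5,
                               clampValue = -20, config = mrclConfig(),
                               permuteLabels = FALSE, maxTries = 50,
                               seed = 1L) {
  design <- match.arg(design)
  out <- lapply(seq_len(nSeeds), function(s) {
    base <- subSeed(seed, 101 * s)
    gs <- NULL; sys <- NULL
    for (tryi in seq_len(maxTries)) {
      sys <- simulateSystem(p = p, edgeDensity = edgeDensity, nObs = nObs,
                            clampValue = clampValue,
                            seed = subSeed(base, tryi))
      gs <- goldStandard(sys@interventionPanel, sys@observational,
                         tau = tau, splitSeed = subSeed(base, 500 + tryi))
      if (sparsityScreen(adjacency(gs), rowwise = design == "rowwise"))
        break
      gs <- NULL
    }
    if (is.null(gs))
      stop("no sampled system passed the sparsity screens; ",
           "weaken the screens or strengthen effects")
    A <- adjacency(gs)
    sampler <- if (design == "rowwise") sampleLabelsRowwise else
      sampleLabelsRandom
    labels <- sampler(A, rho, seed = subSeed(base, 777))
    if (permuteLabels)
      labels@y <- withSeed(subSeed(base, 888), sample(labels@y))
    train <- sys@observational[trainingIndices(gs), , drop = FALSE]
    cfg <- config
    cfg$seed <- subSeed(base, 999)
    res <- runMRCL(train, labels, cfg)
    index <- buildPairIndex(p, varNames = colnames(train))
    ut <- unlabelledTruth(labels, A, index)
    sc <- edgeScores(res)$score[ut$k]
    ev <- rocAuc(sc, ut$truth, testSet = ut$k, design = design, rho = rho)
    data.frame(seed = s, auc = aucValue(ev), nEdges = sum(A),
               mL = length(labelledPairs(labels)), nTest = length(ut$k))
  })
  do.call(rbind, out)
}

#' Null benchmark: independent variables, random labels
#'
#' Simulates mutually independent Gaussian variables and a truth adjacency
#' unrelated to them, runs the full estimator, and scores the unlabelled
#' pairs. Because the features carry no information about the random
#' truth, the expected AUC is 0.5.
#'
#' @param nSeeds number of replicates (default 20).
#' @param p number of variables (default 10).
#' @param n samples (default 300).
#' @param rho label fraction (default 0.3).
#' @param edgeProb edge probability of the random truth (default 0.3).
#' @param config [mrclConfig()] overrides.
#' @param seed master seed.
#' @return data.frame with one AUC per seed.
#' @examples
#' \donttest{
#' mean(nullBenchmark(nSeeds = 3, seed = 1)$auc)
#' }
#' @export
nullBenchmark <- function(nSeeds = 20, p = 10, n = 300, rho = 0.3,
                          edgeProb = 0.3, config = mrclConfig(),
                          seed = 1L) {
  out <- lapply(seq_len(nSeeds), function(s) {
    base <- subSeed(seed, 37 * s)
    dat <- withSeed(subSeed(base, 1), {
      x <- matrix(stats::rnorm(n * p), n, p)
      colnames(x) <- paste0("V", seq_len(p))
      x
    })
    A <- withSeed(subSeed(base, 2), {
      A <- matrix(stats::runif(p * p) < edgeProb, p, p) * 1L
      diag(A) <- 0L
      A
    })
    labels <- sampleLabelsRandom(A, rho, seed = subSeed(base, 3))
    ## a degenerate single-class draw cannot be scored; redraw labels
    tries <- 0
    index <- buildPairIndex(p, varNames = colnames(dat))
    repeat {
      ut <- unlabelledTruth(labels, A, index)
      if (length(unique(ut$truth)) == 2 || tries > 10) break
      tries <- tries + 1
      labels <- sampleLabelsRandom(A, rho, seed = subSeed(base, 3 + tries))
    }
    cfg <- config
    cfg$seed <- subSeed(base, 4)
    res <- runMRCL(dat, labels, cfg)
    sc <- edgeScores(res)$score[ut$k]
    data.frame(seed = s,
               auc = aucValue(rocAuc(sc, ut$truth, testSet = ut$k)))
  })
  do.call(rbind, out)
}
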