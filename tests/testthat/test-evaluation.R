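test_that("gold standard applies the robust z-score with a strict threshold", {
  set.seed(221)
  obs <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  gs0 <- goldStandard(matrix(0, 2, 2), obs, tau = 5, splitSeed = 7)
  ## recompute the reference half statistics independently
  ref <- obs[setdiff(1:40, trainingIndices(gs0)), ]
  med <- apply(ref, 2, median)
  iqr <- apply(ref, 2, IQR)
  ## an effect exactly tau robust units away is NOT an edge (strict)
  zAt <- rbind(c(med[1], med[2] + 5 * iqr[2]),
               c(med[1] + 5.1 * iqr[1], med[2]))
  gs <- goldStandard(zAt, obs, tau = 5, splitSeed = 7)
  expect_equal(zetaScores(gs)[1, 2], 5)
  expect_equal(zetaScores(gs)[2, 1], 5.1)
  expect_identical(adjacency(gs)[1, 2], 0L)     # zeta == tau: no edge
  expect_identical(adjacency(gs)[2, 1], 1L)     # zeta > tau: edge
  ## no change at all: zeta 0, never an edge
  zNull <- rbind(med, med)
  expect_true(all(zetaScores(goldStandard(zNull, obs, splitSeed = 7)) == 0))
  ## the training half is the complement of the reference half
  expect_length(intersect(trainingIndices(gs), which(1:40 %in%
    setdiff(1:40, trainingIndices(gs)))), 0)
  expect_length(trainingIndices(gs), 20)
})

test_that("gold standard rejects degenerate observational spread", {
  obs <- cbind(rnorm(20), rep(2, 20))
  colnames(obs) <- c("ok", "flat")
  expect_error(goldStandard(matrix(0, 2, 2), obs), "IQR.*flat")
  expect_error(goldStandard(matrix(0, 2, 2), matrix(rnorm(8), 4, 2)),
               "at least 8")
})

test_that("random label sampling hits the floor(rho m) bookkeeping", {
  A <- matrix(0L, 50, 50)
  lab <- sampleLabelsRandom(A, rho = 0.2, seed = 1, includeDiagonal = TRUE)
  expect_equal(npairs(lab), 2500)
  expect_length(labelledPairs(lab), 500)
  ## rho = 1 labels everything
  labFull <- sampleLabelsRandom(diag(0, 4), rho = 1, seed = 1)
  expect_length(unlabelledPairs(labFull), 0)
  ## different seeds, same size, different sets
  l1 <- sampleLabelsRandom(A, 0.1, seed = 1)
  l2 <- sampleLabelsRandom(A, 0.1, seed = 2)
  expect_equal(length(labelledPairs(l1)), length(labelledPairs(l2)))
  expect_false(identical(labelledPairs(l1), labelledPairs(l2)))
  expect_error(sampleLabelsRandom(diag(0, 3), rho = 0.01, seed = 1),
               "no labels")
  ## labels reflect the adjacency
  set.seed(5)
  A2 <- (matrix(runif(36), 6, 6) < 0.4) * 1L; diag(A2) <- 0L
  lr <- sampleLabelsRandom(A2, 0.5, seed = 3)
  pm <- pairMatrix(buildPairIndex(6))[labelledPairs(lr), ]
  expect_identical(trainingLabels(lr), ifelse(A2[pm] != 0, 1, -1))
})

test_that("row-wise sampling labels whole rows and leaves whole rows unseen", {
  A <- matrix(0L, 50, 50)
  lab <- sampleLabelsRowwise(A, rho = 0.5, seed = 1)
  idx <- buildPairIndex(50)
  srcL <- unique(pairMatrix(idx)[labelledPairs(lab), 1])
  srcU <- unique(pairMatrix(idx)[unlabelledPairs(lab), 1])
  expect_length(srcL, 25)
  expect_length(intersect(srcL, srcU), 0)
  expect_length(labelledPairs(lab), 25 * 49)
  labFull <- sampleLabelsRowwise(A, rho = 1, seed = 1)
  expect_length(unlabelledPairs(labFull), 0)
  expect_error(sampleLabelsRowwise(A, rho = 0.01, seed = 1), "no rows")
})

test_that("ROC/AUC handles perfect, reversed and tied rankings", {
  ev <- rocAuc(c(9, 8, 2, 1), c(1, 1, 0, 0))
  expect_equal(aucValue(ev), 1)
  expect_equal(aucValue(rocAuc(c(1, 2, 8, 9), c(1, 1, 0, 0))), 0)
  expect_error(rocAuc(1:4, c(1, 1, 1, 1)), "both classes")
  ## absolute mode ranks by |score|
  expect_equal(aucValue(rocAuc(c(-9, 8, 2, -1), c(1, 1, 0, 0),
                               absolute = TRUE)), 1)
})

test_that("midrank AUC equals the trapezoidal ROC area, with ties", {
  set.seed(231)
  for (r in 1:25) {
    n <- sample(20:200, 1)
    scores <- sample(round(rnorm(n), 1))          # coarse: many ties
    truth <- runif(n) < 0.4
    if (length(unique(truth)) < 2) truth[1:2] <- c(TRUE, FALSE)
    ev <- rocAuc(scores, truth)
    expect_equal(aucValue(ev), trapezoidArea(rocPoints(ev)),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an external reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(241)
  scores <- rnorm(150)
  truth <- runif(150) < 0.5
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth,
                                        predictor = scores,
                                        direction = "<", quiet = TRUE)))
  expect_equal(aucValue(rocAuc(scores, truth)), ref, tolerance = 1e-12)
})

test_that("random scores against random truth give chance-level AUC", {
  set.seed(251)
  aucs <- replicate(100, {
    aucValue(rocAuc(rnorm(400), runif(400) < 0.5))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("correlation baselines score pairs symmetrically", {
  set.seed(261)
  x <- cbind(a = rnorm(200), b = rnorm(200))
  x <- cbind(x, c = x[, "a"])                     # identical to a
  idx <- buildPairIndex(3, varNames = colnames(x))
  r <- baselineCorrelation(x, "pearson", idx)
  expect_equal(r[kOf(idx, "a", "c")], 1)
  expect_equal(r[kOf(idx, "a", "b")], r[kOf(idx, "b", "a")])
  ## Kendall is invariant to strictly monotone transforms
  y <- cbind(u = rexp(50))
  y <- cbind(y, v = exp(2 * y[, "u"]))
  rk <- baselineCorrelation(y, "kendall")
  expect_equal(rk[1], 1)
  expect_error(baselineCorrelation(cbind(rnorm(20), rep(1, 20))),
               "zero-variance")
  ## independent variables: small correlations
  z <- matrix(rnorm(1000 * 6), 1000, 6)
  expect_gte(mean(abs(baselineCorrelation(z)) < 0.1), 0.95)
})

test_that("k-NN baseline matches brute-force neighbour votes", {
  set.seed(271)
  z <- standardizeTruncate(matrix(rnorm(200), 50, 4))
  f <- reduceDimension(featurizePairs(z, bins = 8), 10)
  A <- (matrix(runif(16), 4, 4) < 0.5) * 1L; diag(A) <- 0L
  lab <- sampleLabelsRandom(A, rho = 0.6, seed = 5)
  k <- 3
  sc <- baselineKnn(f, lab, k)
  X <- pairFeatures(f)
  L <- labelledPairs(lab)
  oracle <- vapply(unlabelledPairs(lab), function(u) {
    d <- sqrt(colSums((t(X[L, ]) - X[u, ])^2))
    mean(trainingLabels(lab)[order(d, L)][1:k])
  }, numeric(1))
  expect_equal(sc, oracle, tolerance = 1e-10)
  ## k = m_L: every score is the mean training label
  scAll <- baselineKnn(f, lab, length(L))
  expect_true(all(abs(scAll - mean(trainingLabels(lab))) < 1e-12))
  expect_error(baselineKnn(f, lab, length(L) + 1), "exceeds")
  ## k = 1 on a duplicated feature row copies that label
  X2 <- rbind(c(0, 0), c(5, 5), c(0, 0))
  lab2 <- new("PartialLabels", labelled = 1:2, y = c(1, -1), nPairs = 3L,
              semantics = "unspecified")
  expect_equal(baselineKnn(X2, lab2, 1), 1)
})

test_that("evaluation is confined to unlabelled, non-self pairs", {
  idx <- buildPairIndex(4, includeDiagonal = TRUE)
  A <- (matrix(runif(16), 4, 4) < 0.5) * 1L
  lab <- sampleLabelsRandom(A, rho = 0.3, seed = 2, includeDiagonal = TRUE)
  ut <- unlabelledTruth(lab, A, idx)
  expect_length(intersect(ut$k, labelledPairs(lab)), 0)
  pm <- pairMatrix(idx)[ut$k, , drop = FALSE]
  expect_true(all(pm[, 1] != pm[, 2]))
  expect_equal(ut$truth, A[pm] != 0)
})

test_that("sparsity screens implement the selection rules", {
  p <- 10
  A <- matrix(0L, p, p)
  expect_false(sparsityScreen(A))
  ## exactly 2.5% of off-diagonal pairs: accepted (at least)
  need <- ceiling(0.025 * p * (p - 1))
  A[cbind(rep(1, need), 2:(need + 1))] <- 1L
  expect_true(sparsityScreen(A))
  ## row-wise screen additionally needs half the rows covered
  expect_false(sparsityScreen(A, rowwise = TRUE))
  A2 <- matrix(0L, p, p)
  for (i in 1:5) A2[i, i %% p + 1] <- 1L
  expect_true(sparsityScreen(A2, rowwise = TRUE))
  expect_false(sparsityScreen(A2[1:8, 1:8] * 0 + diag(0L, 8), rowwise = TRUE))
})
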