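## Interventional gold standards, label-sampling designs, ROC/AUC, and
## simple baselines.

#' Interventional gold standard via robust z-scores
#'
#' Declares a causal effect of variable i on variable j when the
#' measurement of j after intervening on i deviates from j's observational
#' centre by more than \code{tau} robust units:
#' \code{zeta[i, j] = |Zint[i, j] - median_j| / IQR_j > tau} (strict).
#' Medians and IQRs are computed from a random half of the observational
#' samples (seeded); the other half is reserved as training data and
#' exposed via [trainingIndices()]. Quantiles use the linear-interpolation
#' convention (R type 7).
#'
#' @param interventionEffects numeric p x p matrix; row i holds the
#'   measurements of every variable in the experiment intervening on
#'   variable i (one value per intervened pair; aggregate replicates
#'   beforehand if you have them).
#' @param observational numeric matrix, samples x variables, at least 8
#'   samples (so the half used for medians/IQRs has >= 4).
#' @param tau positive threshold (default 5).
#' @param splitSeed integer seed of the observational half-split.
#' @param includeDiagonal logical; keep self-effects on the adjacency
#'   diagonal (default \code{FALSE}).
#' @return A [GoldStandard-class].
#' @examples
#' obs <- matrix(rnorm(80), 40, 2)
#' zint <- matrix(c(0, 8, 8, 0), 2, 2)
#' adjacency(goldStandard(zint, obs, tau = 5))
#' @export
goldStandard <- function(interventionEffects, observational, tau = 5,
                         splitSeed = 1L, includeDiagonal = FALSE) {
  Zint <- as.matrix(interventionEffects)
  obs <- as.matrix(observational)
  p <- ncol(obs)
  if (!all(dim(Zint) == p))
    stop("interventionEffects must be p x p matching the observational matrix")
  if (tau <= 0) stop("tau must be positive")
  n <- nrow(obs)
  if (n < 8) stop("need at least 8 observational samples for the half-split")
  half <- withSeed(splitSeed, sample.int(n, floor(n / 2)))
  ref <- obs[half, , drop = FALSE]
  med <- apply(ref, 2, stats::median)
  iqr <- apply(ref, 2, stats::IQR, type = 7)
  if (any(iqr == 0)) {
    bad <- which(iqr == 0)[1]
    stop(sprintf("zero observational IQR for variable %s",
                 colnames(obs)[bad] %||% bad))
  }
  zeta <- abs(sweep(Zint, 2, med)) / rep(iqr, each = p)
  adj <- (zeta > tau) * 1L
  if (!includeDiagonal) diag(adj) <- 0L
  dimnames(zeta) <- dimnames(adj) <- list(colnames(obs), colnames(obs))
  new("GoldStandard", zeta = zeta, adjacency = adj, tau = tau,
      splitSeed = as.integer(splitSeed), medians = med, iqrs = iqr,
      trainIdx = setdiff(seq_len(n), half))
}

#' Sparsity screens for gold-standard adjacencies
#'
#' Selection rules for accepting a variable subset: at least
#' \code{minPairFraction} of the off-diagonal pairs must show an effect
#' and, for row-wise designs, at least \code{minRowFraction} of the rows
#' must contain at least one effect.
#'
#' @param adjacency binary p x p matrix.
#' @param minPairFraction minimum fraction of off-diagonal pairs with an
#'   effect (default 0.025).
#' @param rowwise logical; also require row coverage (default
#'   \code{FALSE}).
#' @param minRowFraction minimum fraction of rows with >= 1 effect
#'   (default 0.5).
#' @return logical scalar.
#' @examples
#' sparsityScreen(diag(0, 4))
#' @export
sparsityScreen <- function(adjacency, minPairFraction = 0.025,
                           rowwise = FALSE, minRowFraction = 0.5) {
  A <- as.matrix(adjacency) != 0
  diag(A) <- FALSE
  p <- nrow(A)
  ok <- sum(A) >= minPairFraction * p * (p - 1)
  if (rowwise)
    ok <- ok && mean(apply(A, 1, any)) >= minRowFraction
  ok
}

#' Sample labels uniformly over pairs
#'
#' Samples \code{floor(rho * m)} pairs without replacement as the labelled
#' set, labels read from the adjacency (+1 for an edge, -1 otherwise); the
#' remainder is the unlabelled set.
#'
#' @param adjacency binary p x p matrix.
#' @param rho label fraction in (0, 1].
#' @param seed integer seed.
#' @param includeDiagonal logical; enumerate self-pairs (then
#'   \code{m = p^2}).
#' @param semantics label semantics tag (default \code{"ancestral"}).
#' @return A [PartialLabels-class].
#' @examples
#' lab <- sampleLabelsRandom(diag(0, 50), rho = 0.2, seed = 1,
#'                           includeDiagonal = TRUE)
#' length(labelledPairs(lab))   # floor(0.2 * 2500) = 500
#' @export
sampleLabelsRandom <- function(adjacency, rho, seed = 1L,
                               includeDiagonal = FALSE,
                               semantics = "ancestral") {
  A <- as.matrix(adjacency)
  p <- nrow(A)
  if (ncol(A) != p) stop("adjacency must be square")
  index <- buildPairIndex(p, includeDiagonal,
                          varNames = colnames(A) %||% paste0("V", 1:p))
  m <- npairs(index)
  mL <- floor(rho * m)
  if (mL < 1) stop("floor(rho * m) = 0: no labels would be sampled")
  k <- withSeed(seed, sort(sample.int(m, mL)))
  pm <- index@pairs[k, , drop = FALSE]
  y <- ifelse(A[pm] != 0, 1, -1)
  if (includeDiagonal) y[pm[, 1] == pm[, 2]] <- 1
  new("PartialLabels", labelled = k, y = as.numeric(y),
      nPairs = m, semantics = semantics)
}

#' Sample labels by entire rows of the adjacency
#'
#' Samples \code{floor(rho * p)} source variables; every pair whose source
#' is sampled is labelled, so the unlabelled set consists of entire rows.
#' This design tests generalization to interventions on wholly unseen
#' source variables.
#'
#' @inheritParams sampleLabelsRandom
#' @return A [PartialLabels-class].
#' @examples
#' lab <- sampleLabelsRowwise(diag(0, 10), rho = 0.5, seed = 1)
#' length(labelledPairs(lab))   # 5 rows x 9 targets
#' @export
sampleLabelsRowwise <- function(adjacency, rho, seed = 1L,
                                includeDiagonal = FALSE,
                                semantics = "ancestral") {
  A <- as.matrix(adjacency)
  p <- nrow(A)
  if (ncol(A) != p) stop("adjacency must be square")
  nRows <- floor(rho * p)
  if (nRows < 1) stop("floor(rho * p) = 0: no rows would be sampled")
  rows <- withSeed(seed, sort(sample.int(p, nRows)))
  index <- buildPairIndex(p, includeDiagonal,
                          varNames = colnames(A) %||% paste0("V", 1:p))
  k <- which(index@pairs[, 1] %in% rows)
  pm <- index@pairs[k, , drop = FALSE]
  y <- ifelse(A[pm] != 0, 1, -1)
  if (includeDiagonal) y[pm[, 1] == pm[, 2]] <- 1
  new("PartialLabels", labelled = k, y = as.numeric(y),
      nPairs = npairs(index), semantics = semantics)
}

#' ROC curve and AUC for edge scores
#'
#' Ranks test pairs by score (optionally by absolute score, appropriate for
#' signed symmetric baselines such as correlations) against binary truth.
#' The AUC is the midrank Mann-Whitney statistic, which equals the
#' trapezoidal area under the returned ROC curve (ties traverse the tie
#' block diagonally).
#'
#' @param scores numeric scores on the test pairs.
#' @param truth logical/binary truth for the same pairs; both classes must
#'   be present.
#' @param absolute rank by \code{|score|} (default \code{FALSE}: raw
#'   scores, the convention for the transductive classifier).
#' @param testSet optional integer ids of the pairs evaluated (bookkeeping
#'   only).
#' @param design,rho bookkeeping fields for the sampling design.
#' @return An [EvalResult-class].
#' @examples
#' aucValue(rocAuc(c(3, 2, 1, 0), c(1, 1, 0, 0)))   # 1
#' @export
rocAuc <- function(scores, truth, absolute = FALSE, testSet = integer(0),
                   design = "custom", rho = NA_real_) {
  truth <- as.logical(truth != 0)
  if (length(scores) != length(truth)) stop("length mismatch")
  if (anyNA(scores) || anyNA(truth)) stop("missing scores or truth")
  nPos <- sum(truth); nNeg <- sum(!truth)
  if (nPos == 0 || nNeg == 0)
    stop("truth must contain both classes")
  s <- if (absolute) abs(scores) else as.numeric(scores)
  ## midrank Mann-Whitney AUC
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[truth]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  ## ROC: step through distinct thresholds, high to low
  o <- order(s, decreasing = TRUE)
  ss <- s[o]; tt <- truth[o]
  grp <- cumsum(c(TRUE, diff(ss) != 0))
  tp <- cumsum(tt); fp <- cumsum(!tt)
  last <- which(c(diff(grp) != 0, TRUE))
  roc <- data.frame(fpr = c(0, fp[last] / nNeg),
                    tpr = c(0, tp[last] / nPos))
  new("EvalResult", auc = auc, roc = roc,
      testSet = as.integer(testSet), design = design,
      rho = as.numeric(rho))
}

#' Truth vector for the unlabelled pairs
#'
#' Reads the gold-standard adjacency at every unlabelled pair, asserting
#' that the evaluation set is disjoint from the training labels (all
#' assessment is with respect to relationships not used for training).
#' Self-pairs are never part of the test partition.
#'
#' @param labels [PartialLabels-class].
#' @param adjacency binary p x p truth matrix.
#' @param index [PairIndex-class] matching \code{labels}.
#' @return list with \code{k} (unlabelled pair indices, self-pairs
#'   removed) and \code{truth} (logical vector).
#' @examples
#' idx <- buildPairIndex(3)
#' lab <- sampleLabelsRandom(diag(0, 3), rho = 0.5, seed = 1)
#' unlabelledTruth(lab, matrix(1, 3, 3), idx)
#' @export
unlabelledTruth <- function(labels, adjacency, index) {
  stopifnot(is(labels, "PartialLabels"), is(index, "PairIndex"))
  if (labels@nPairs != npairs(index)) stop("labels/index mismatch")
  U <- unlabelledPairs(labels)
  if (length(intersect(U, labels@labelled)))
    stop("test set overlaps the training labels")
  pm <- index@pairs[U, , drop = FALSE]
  keep <- pm[, 1] != pm[, 2]
  U <- U[keep]; pm <- pm[keep, , drop = FALSE]
  list(k = U, truth = as.matrix(adjacency)[pm] != 0)
}

#' Correlation baseline scores
#'
#' Scores every ordered pair by the Pearson or Kendall correlation of its
#' two variables. The score is symmetric (both orientations receive the
#' same value); take absolute values at evaluation time
#' (\code{rocAuc(..., absolute = TRUE)}).
#'
#' @param data numeric matrix, samples x variables (n >= 3).
#' @param method \code{"pearson"} or \code{"kendall"}.
#' @param index optional [PairIndex-class] (default: all ordered
#'   non-diagonal pairs).
#' @return numeric score vector over the enumerated pairs.
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' head(baselineCorrelation(x))
#' @export
baselineCorrelation <- function(data, method = c("pearson", "kendall"),
                                index = NULL) {
  method <- match.arg(method)
  data <- as.matrix(data)
  if (nrow(data) < 3) stop("need at least 3 samples")
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    stop(sprintf("zero-variance variable: %s",
                 colnames(data)[bad] %||% bad))
  }
  if (is.null(index)) index <- buildPairIndex(ncol(data),
                                              varNames = colnames(data))
  C <- stats::cor(data, method = method)
  C[index@pairs]
}

#' k-nearest-neighbour baseline on pair features
#'
#' Scores each unlabelled pair by the mean label of its k nearest labelled
#' pairs in Euclidean feature space; ties in distance are broken
#' deterministically by pair index.
#'
#' @param feats [PairFeatureMatrix-class] (rows in pair-index order).
#' @param labels [PartialLabels-class].
#' @param k positive integer, \code{k <= m_L}.
#' @return numeric scores for the unlabelled pairs, in the order of
#'   \code{unlabelledPairs(labels)}.
#' @examples
#' z <- standardizeTruncate(matrix(rnorm(200), 50, 4))
#' f <- featurizePairs(z)
#' lab <- sampleLabelsRandom(diag(0, 4), rho = 0.5, seed = 1)
#' baselineKnn(f, lab, k = 2)
#' @export
baselineKnn <- function(feats, labels, k) {
  stopifnot(is(labels, "PartialLabels"))
  X <- if (is(feats, "PairFeatureMatrix")) feats@features else as.matrix(feats)
  if (nrow(X) != labels@nPairs) stop("features/labels mismatch")
  L <- labels@labelled
  if (k > length(L)) stop("k exceeds the number of labelled pairs")
  if (k < 1) stop("k must be positive")
  U <- unlabelledPairs(labels)
  XL <- X[L, , drop = FALSE]
  sqL <- rowSums(XL^2)
  vapply(U, function(u) {
    d2 <- sqL + sum(X[u, ]^2) - 2 * drop(XL %*% X[u, ])
    o <- order(d2, L)                     # deterministic tie-break
    mean(labels@y[o[seq_len(k)]])
  }, numeric(1))
}
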