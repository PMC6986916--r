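## Orchestration of the full estimator: pair indexing, label assembly,
## featurize -> manifold graph -> transduce -> classify -> graph assembly.

#' Build the linear index over ordered variable pairs
#'
#' Deterministic row-major enumeration: all ordered pairs with source 1
#' first, then source 2, and so on. Self-pairs are excluded by default
#' (\code{m = p(p-1)}); including the diagonal reproduces \code{m = p^2}
#' bookkeeping, in which case self-pairs are auto-labelled +1 by
#' [assembleLabels()] and excluded from test partitions by the samplers.
#'
#' @param p integer number of variables (>= 2).
#' @param includeDiagonal logical (default \code{FALSE}).
#' @param varNames optional character vector of variable names.
#' @return A [PairIndex-class].
#' @examples
#' npairs(buildPairIndex(3))              # 6
#' npairs(buildPairIndex(50, TRUE))       # 2500
#' @export
buildPairIndex <- function(p, includeDiagonal = FALSE, varNames = NULL) {
  p <- as.integer(p)
  if (is.na(p) || p < 2) stop("p must be at least 2")
  if (is.null(varNames)) varNames <- paste0("V", seq_len(p))
  if (length(varNames) != p) stop("varNames length must equal p")
  i <- rep(seq_len(p), each = p)
  j <- rep(seq_len(p), times = p)
  if (!includeDiagonal) {
    keep <- i != j
    i <- i[keep]; j <- j[keep]
  }
  pm <- cbind(i, j)
  dimnames(pm) <- list(NULL, c("source", "target"))
  lookup <- matrix(NA_integer_, p, p)
  lookup[pm] <- seq_len(nrow(pm))
  new("PairIndex", p = p, varNames = as.character(varNames),
      includeDiagonal = isTRUE(includeDiagonal), pairs = pm,
      lookup = lookup)
}

#' Linear index of an ordered pair
#'
#' Inverse of the enumeration in [buildPairIndex()]:
#' \code{kOf(idx, i, j)} returns k with
#' \code{pairMatrix(idx)[k, ] == c(i, j)}.
#'
#' @param index a [PairIndex-class].
#' @param i,j variable indices or names.
#' @return integer linear index.
#' @examples
#' idx <- buildPairIndex(4)
#' kOf(idx, 2, 3)
#' @export
kOf <- function(index, i, j) {
  stopifnot(is(index, "PairIndex"))
  if (is.character(i)) i <- match(i, index@varNames)
  if (is.character(j)) j <- match(j, index@varNames)
  if (anyNA(i) || anyNA(j) || any(i < 1 | i > index@p | j < 1 | j > index@p))
    stop("unknown variable")
  k <- index@lookup[cbind(i, j)]
  if (anyNA(k)) stop("pair not enumerated (diagonal excluded?)")
  k
}

#' Assemble partial labels from a labelled edge list
#'
#' Maps each labelled edge (source, target, label) to its pair index; all
#' remaining pairs form the unlabelled set. Duplicated edges with agreeing
#' labels collapse to one; conflicting duplicates are an error. When both
#' orientations of a pair are labelled +1 a note is emitted (a mutual
#' causal pair, i.e. a 2-cycle, which is permitted but worth flagging); no
#' constraint is applied. With a diagonal-including index, self-pairs are
#' auto-labelled +1.
#'
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{label} (labels in \{-1, +1\}); source/target may be names or
#'   indices.
#' @param index a [PairIndex-class].
#' @param semantics \code{"ancestral"}, \code{"direct"} or
#'   \code{"unspecified"}: what relation the labels encode (default
#'   \code{"ancestral"}, the interventional case).
#' @return A [PartialLabels-class].
#' @examples
#' idx <- buildPairIndex(3, varNames = c("a", "b", "c"))
#' assembleLabels(data.frame(source = "a", target = "b", label = 1), idx)
#' @export
assembleLabels <- function(edges, index,
                           semantics = c("ancestral", "direct",
                                         "unspecified")) {
  stopifnot(is(index, "PairIndex"))
  semantics <- match.arg(semantics)
  edges <- as.data.frame(edges)
  if (!all(c("source", "target", "label") %in% names(edges)))
    stop("edges must have columns source, target, label")
  if (nrow(edges) == 0)
    stop("no labelled edges: the estimator is undefined without background knowledge")
  if (!all(edges$label %in% c(-1, 1)))
    stop("labels must lie in {-1, +1}")
  k <- kOf(index, edges$source, edges$target)
  agg <- tapply(edges$label, k, function(v) {
    u <- unique(v)
    if (length(u) > 1) NA_real_ else u
  })
  if (anyNA(agg)) {
    bad <- as.integer(names(agg))[is.na(agg)][1]
    stop(sprintf("conflicting duplicate labels for pair (%s, %s)",
                 index@varNames[index@pairs[bad, 1]],
                 index@varNames[index@pairs[bad, 2]]))
  }
  labelled <- as.integer(names(agg))
  y <- as.numeric(agg)
  ## flag mutual +1 orientations (possible causal cycle)
  pos <- labelled[y > 0]
  if (length(pos)) {
    pm <- index@pairs[pos, , drop = FALSE]
    rev <- index@lookup[pm[, 2:1, drop = FALSE]]
    if (any(!is.na(rev) & rev %in% pos & pm[, 1] < pm[, 2]))
      message("note: some pairs are labelled causal in both orientations (cycle)")
  }
  if (index@includeDiagonal) {
    dk <- index@lookup[cbind(seq_len(index@p), seq_len(index@p))]
    extra <- setdiff(dk, labelled)
    labelled <- c(labelled, extra)
    y <- c(y, rep(1, length(extra)))
    o <- order(labelled)
    labelled <- labelled[o]; y <- y[o]
  }
  new("PartialLabels", labelled = labelled, y = y,
      nPairs = npairs(index), semantics = semantics)
}

#' Configuration for the MRCL estimator
#'
#' Collects the tunable parameters of the pipeline with their defaults:
#' truncation bounds [-3, 3], histogram bin width 0.2 (30 bins per axis),
#' PCA to 100 dimensions, length scale estimated as the average distance to
#' the nearest 50 feature points over a subsample of 1000, kernel scale
#' equal to the similarity scale, penalty weights
#' \code{lambda1 = lambda2 = 0.001}, and the normalized graph Laplacian.
#'
#' @param bounds numeric length-2 truncation interval.
#' @param binWidth histogram bin width on the standardized scale.
#' @param pcaDim number of principal components retained.
#' @param sigma1 similarity length scale, or \code{NULL} to estimate.
#' @param sigma2 kernel length scale, or \code{NULL} for \code{sigma1}.
#' @param knnForScale neighbours used by the length-scale heuristic.
#' @param scaleSubsample subsample size for the length-scale heuristic.
#' @param lambda1 manifold penalty weight.
#' @param lambda2 RKHS-norm penalty weight.
#' @param useNormalizedLaplacian logical.
#' @param includeDiagonal logical; enumerate self-pairs.
#' @param seed integer seed for every stochastic step.
#' @return a named list of class \code{"mrclConfig"}.
#' @examples
#' mrclConfig(pcaDim = 50)$pcaDim
#' @export
mrclConfig <- function(bounds = c(-3, 3), binWidth = 0.2, pcaDim = 100L,
                       sigma1 = NULL, sigma2 = NULL, knnForScale = 50L,
                       scaleSubsample = 1000L, lambda1 = 0.001,
                       lambda2 = 0.001, useNormalizedLaplacian = TRUE,
                       includeDiagonal = FALSE, seed = 1L) {
  cfg <- list(bounds = bounds, binWidth = binWidth, pcaDim = pcaDim,
              sigma1 = sigma1, sigma2 = sigma2, knnForScale = knnForScale,
              scaleSubsample = scaleSubsample, lambda1 = lambda1,
              lambda2 = lambda2,
              useNormalizedLaplacian = useNormalizedLaplacian,
              includeDiagonal = includeDiagonal, seed = seed)
  class(cfg) <- "mrclConfig"
  cfg
}

#' Run the full MRCL estimator
#'
#' Executes the pipeline: standardize/truncate, histogram featurization of
#' every ordered pair, PCA reduction, length-scale estimation, similarity /
#' kernel / Laplacian construction, closed-form transduction, sign
#' classification, and assembly of the directed graph whose edges are
#' exactly the pairs with estimated (or known) label +1. Fully reproducible
#' from the configuration and seed; errors are tagged with the stage that
#' raised them.
#'
#' @param data numeric matrix, samples x variables, with column names
#'   covering every variable referenced by \code{labels}.
#' @param labels [PartialLabels-class] over the pair enumeration implied by
#'   \code{ncol(data)} and \code{config$includeDiagonal}.
#' @param config a list from [mrclConfig()].
#' @return An [MRCLResult-class].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), 100, 6,
#'             dimnames = list(NULL, paste0("g", 1:6)))
#' idx <- buildPairIndex(6, varNames = colnames(x))
#' lab <- assembleLabels(data.frame(source = c("g1", "g2", "g3", "g4"),
#'                                  target = c("g2", "g3", "g4", "g5"),
#'                                  label = c(1, -1, 1, -1)), idx)
#' res <- runMRCL(x, lab, mrclConfig(pcaDim = 10))
#' head(edgeScores(res))
#' @export
runMRCL <- function(data, labels, config = mrclConfig()) {
  stopifnot(is(labels, "PartialLabels"))
  data <- as.matrix(data)
  if (is.null(colnames(data)))
    colnames(data) <- paste0("V", seq_len(ncol(data)))
  index <- buildPairIndex(ncol(data), config$includeDiagonal,
                          varNames = colnames(data))
  if (npairs(index) != labels@nPairs)
    stop("labels were built for a different pair enumeration")
  M <- as.integer(round(diff(config$bounds) / config$binWidth))

  z <- stageCall("standardize_truncate",
                 standardizeTruncate(data, config$bounds))
  feats <- stageCall("featurize_pairs",
                     featurizePairs(z, index, bins = M,
                                    bounds = config$bounds))
  feats <- stageCall("reduce_dimension",
                     reduceDimension(feats, config$pcaDim))

  ## partition ordering: labelled pairs first
  L <- labels@labelled
  U <- unlabelledPairs(labels)
  perm <- c(L, U)
  X <- feats@features[perm, , drop = FALSE]

  sigma1 <- config$sigma1
  if (is.null(sigma1))
    sigma1 <- stageCall("estimate_length_scale",
                        estimateLengthScale(X, config$knnForScale,
                                            config$scaleSubsample,
                                            config$seed))
  sigma2 <- config$sigma2 %||% sigma1

  graph <- stageCall("manifold_graph", manifoldGraph(X, sigma1 = sigma1))
  Lmat <- laplacian(graph, normalized = config$useNormalizedLaplacian)
  kern <- stageCall("kernel_matrix",
                    kernelMatrix(X, sigma2, nLabelled = length(L)))
  fit <- stageCall("fit_transduce",
                   fitTransduce(kern, Lmat, labels@y,
                                lambda1 = config$lambda1,
                                lambda2 = config$lambda2))
  yU <- classifyPairs(fit, "unlabelled")
  fAll <- fittedScores(fit, "all")

  ## reassemble in pair-index order
  score <- numeric(npairs(index))
  score[perm] <- fAll
  predicted <- numeric(npairs(index))
  predicted[L] <- labels@y
  predicted[U] <- yU
  pm <- index@pairs
  scores <- data.frame(
    source = index@varNames[pm[, 1]],
    target = index@varNames[pm[, 2]],
    k = seq_len(npairs(index)),
    score = score,
    predictedLabel = predicted,
    labelled = seq_len(npairs(index)) %in% L,
    stringsAsFactors = FALSE)

  edgeRows <- scores[scores$predictedLabel > 0, , drop = FALSE]
  graphOut <- new("CausalGraph", vertices = index@varNames,
                  edges = data.frame(source = edgeRows$source,
                                     target = edgeRows$target,
                                     score = edgeRows$score,
                                     labelled = edgeRows$labelled,
                                     stringsAsFactors = FALSE),
                  semantics = labels@semantics)
  cfg <- unclass(config)
  cfg$sigma1 <- sigma1
  cfg$sigma2 <- sigma2
  new("MRCLResult", scores = scores, graph = graphOut, sigma1 = sigma1,
      config = cfg, diagnostics = fit@diagnostics[c("residual",
                                                    "conditionEstimate")])
}
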