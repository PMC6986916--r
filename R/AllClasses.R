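#' @import methods
NULL

#' PairIndex: linear indexing of ordered variable pairs
#'
#' A bijection between linear indices \code{k = 1..m} and ordered variable
#' pairs \code{(i, j)} over \code{p} named variables, enumerated row-major
#' (all targets of variable 1, then of variable 2, ...). Self-pairs
#' \code{(i, i)} are included only when \code{includeDiagonal} is set, in
#' which case \code{m = p^2}; otherwise \code{m = p(p-1)}.
#'
#' @slot p integer, number of variables.
#' @slot varNames character vector of length \code{p}.
#' @slot includeDiagonal logical scalar.
#' @slot pairs integer matrix \code{m x 2} of (source, target) indices.
#' @slot lookup integer matrix \code{p x p} mapping \code{(i, j)} to the
#'   linear index \code{k}, \code{NA} for pairs not enumerated.
#'
#' @seealso [buildPairIndex()], [kOf()]
#' @export
setClass("PairIndex",
  slots = c(p = "integer", varNames = "character",
            includeDiagonal = "logical", pairs = "matrix",
            lookup = "matrix"))

setValidity("PairIndex", function(object) {
  m <- nrow(object@pairs)
  want <- if (object@includeDiagonal) object@p^2 else object@p * (object@p - 1L)
  if (m != want)
    return(sprintf("pair count %d does not match p = %d (diagonal %s)",
                   m, object@p, object@includeDiagonal))
  if (length(object@varNames) != object@p)
    return("varNames length must equal p")
  k <- object@lookup[object@pairs]
  if (!identical(k, seq_len(m)))
    return("lookup is not the inverse of the pair enumeration")
  TRUE
})

#' PartialLabels: labelled / unlabelled partition of pairs
#'
#' Encodes background knowledge: the subset of pair indices whose causal
#' status is known, with labels in \{-1, +1\}; all remaining pairs are the
#' unlabelled set whose labels are to be estimated.
#'
#' @slot labelled integer vector of labelled pair indices (k).
#' @slot y numeric vector of labels in \{-1, +1\}, parallel to
#'   \code{labelled}.
#' @slot nPairs integer, total number of pairs m.
#' @slot semantics character, one of \code{"ancestral"}, \code{"direct"},
#'   \code{"unspecified"}; records what kind of causal relation the labels
#'   encode and is carried through to the estimated graph unchanged.
#'
#' @seealso [assembleLabels()], [sampleLabelsRandom()], [sampleLabelsRowwise()]
#' @export
setClass("PartialLabels",
  slots = c(labelled = "integer", y = "numeric", nPairs = "integer",
            semantics = "character"))

setValidity("PartialLabels", function(object) {
  if (length(object@labelled) != length(object@y))
    return("labelled and y must have equal length")
  if (anyDuplicated(object@labelled))
    return("duplicate labelled pair indices")
  if (length(object@labelled) &&
      (min(object@labelled) < 1L || max(object@labelled) > object@nPairs))
    return("labelled indices out of range")
  if (!all(object@y %in% c(-1, 1)))
    return("labels must lie in {-1, +1}")
  if (!object@semantics %in% c("ancestral", "direct", "unspecified"))
    return("semantics must be 'ancestral', 'direct' or 'unspecified'")
  TRUE
})

#' HistogramDensity: bivariate histogram density estimate
#'
#' Bin counts of a bivariate scatter plot on a regular \code{M x M} grid over
#' a square domain. The density estimate on bin \code{(m1, m2)} is
#' \code{counts[m1, m2] / (n * h^2)} where \code{h} is the bin width, so the
#' estimate integrates to one.
#'
#' @slot counts integer-valued matrix \code{M x M}; rows index the first
#'   coordinate, columns the second.
#' @slot bins integer, bins per axis (M).
#' @slot binWidth numeric bin width \code{h = (z_max - z_min) / M}.
#' @slot bounds numeric length-2, \code{c(z_min, z_max)}.
#' @slot nPoints integer, number of points binned.
#'
#' @seealso [histogramDensity()], [histogramDistance()]
#' @export
setClass("HistogramDensity",
  slots = c(counts = "matrix", bins = "integer", binWidth = "numeric",
            bounds = "numeric", nPoints = "integer"))

setValidity("HistogramDensity", function(object) {
  if (!all(dim(object@counts) == object@bins))
    return("counts must be bins x bins")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    return("counts must be non-negative integers")
  if (sum(object@counts) != object@nPoints)
    return("counts must sum to the number of points")
  h <- diff(object@bounds) / object@bins
  if (abs(h - object@binWidth) > 1e-12)
    return("binWidth inconsistent with bounds and bins")
  TRUE
})

#' PairFeatureMatrix: per-pair feature table
#'
#' One feature row per ordered pair. At the \code{"raw"} stage rows are
#' vectorized histogram bin counts (length \code{M^2}, each row summing to
#' the sample size n); at the \code{"pca"} stage rows are scores on the
#' leading principal components, with the centering vector and loadings
#' retained.
#'
#' @slot features numeric matrix \code{m x d}.
#' @slot pairIndex [PairIndex-class] describing the rows.
#' @slot stage character, \code{"raw"} or \code{"pca"}.
#' @slot nPoints integer, points per scatter plot (n).
#' @slot bins integer, bins per axis at the raw stage.
#' @slot bounds numeric length-2 domain bounds.
#' @slot center numeric centering vector (pca stage; length 0 otherwise).
#' @slot rotation numeric loading matrix (pca stage; 0 x 0 otherwise).
#'
#' @seealso [featurizePairs()], [reduceDimension()]
#' @export
setClass("PairFeatureMatrix",
  slots = c(features = "matrix", pairIndex = "PairIndex",
            stage = "character", nPoints = "integer", bins = "integer",
            bounds = "numeric", center = "numeric", rotation = "matrix"))

setValidity("PairFeatureMatrix", function(object) {
  if (nrow(object@features) != nrow(object@pairIndex@pairs))
    return("feature row count must equal the pair count")
  if (!object@stage %in% c("raw", "pca"))
    return("stage must be 'raw' or 'pca'")
  if (object@stage == "raw") {
    if (ncol(object@features) != object@bins^2)
      return("raw features must have M^2 columns")
    if (any(abs(rowSums(object@features) - object@nPoints) > 1e-9))
      return("raw feature rows must sum to the sample size")
  }
  TRUE
})

#' ManifoldGraph: similarity graph over pairs
#'
#' Squared-exponential similarity matrix W over pair features, with degrees,
#' unnormalized Laplacian L = D - W, and normalized Laplacian
#' D^{-1/2} L D^{-1/2}.
#'
#' @slot W numeric \code{m x m} similarity matrix, symmetric, unit diagonal.
#' @slot degrees numeric row sums of W.
#' @slot laplacian numeric \code{m x m} unnormalized Laplacian.
#' @slot laplacianNorm numeric \code{m x m} normalized Laplacian.
#' @slot sigma1 positive length scale used for W.
#'
#' @seealso [manifoldGraph()], [similarityMatrix()], [graphLaplacian()]
#' @export
setClass("ManifoldGraph",
  slots = c(W = "matrix", degrees = "numeric", laplacian = "matrix",
            laplacianNorm = "matrix", sigma1 = "numeric"))

setValidity("ManifoldGraph", function(object) {
  m <- nrow(object@W)
  if (ncol(object@W) != m) return("W must be square")
  if (max(abs(object@W - t(object@W))) > 1e-10) return("W must be symmetric")
  if (any(object@W <= 0) || any(object@W > 1 + 1e-12))
    return("W entries must lie in (0, 1]")
  if (max(abs(diag(object@W) - 1)) > 1e-12) return("W diagonal must be 1")
  if (max(abs(object@degrees - rowSums(object@W))) > 1e-8)
    return("degrees must be the row sums of W")
  if (object@sigma1 <= 0) return("sigma1 must be positive")
  TRUE
})

#' KernelMatrix: Mercer kernel evaluations over pairs
#'
#' Squared-exponential kernel matrix over pair features, with the number of
#' labelled rows recorded so the labelled-block / unlabelled-block partition
#' (labelled pairs first) can be sliced.
#'
#' @slot K numeric \code{m x m} symmetric PSD matrix with unit diagonal.
#' @slot sigma2 positive length scale.
#' @slot nLabelled integer, number of leading rows that are labelled pairs
#'   (may be \code{NA} until the partition is fixed).
#'
#' @seealso [kernelMatrix()], [fitTransduce()]
#' @export
setClass("KernelMatrix",
  slots = c(K = "matrix", sigma2 = "numeric", nLabelled = "integer"))

setValidity("KernelMatrix", function(object) {
  if (nrow(object@K) != ncol(object@K)) return("K must be square")
  if (max(abs(object@K - t(object@K))) > 1e-10) return("K must be symmetric")
  if (max(abs(diag(object@K) - 1)) > 1e-12) return("K diagonal must be 1")
  if (object@sigma2 <= 0) return("sigma2 must be positive")
  TRUE
})

#' LapRLSFit: fitted transductive classifier
#'
#' Real-valued scores at all m pairs from the closed-form solution of the
#' Laplacian-regularized least-squares problem, in partition order (labelled
#' pairs first). Scores at unlabelled pairs are the estimator's output;
#' scores at labelled pairs are in-sample values kept for diagnostics only.
#'
#' @slot fHat numeric length-m score vector (partition order).
#' @slot nLabelled integer, number of labelled pairs.
#' @slot yTrain numeric labels used for fitting.
#' @slot lambda1 numeric manifold penalty weight.
#' @slot lambda2 numeric RKHS-norm penalty weight.
#' @slot diagnostics list: \code{residual} (relative residual of the linear
#'   solve) and \code{conditionEstimate}.
#'
#' @seealso [fitTransduce()], [classifyPairs()]
#' @export
setClass("LapRLSFit",
  slots = c(fHat = "numeric", nLabelled = "integer", yTrain = "numeric",
            lambda1 = "numeric", lambda2 = "numeric", diagnostics = "list"))

setValidity("LapRLSFit", function(object) {
  if (length(object@yTrain) != object@nLabelled)
    return("yTrain length must equal nLabelled")
  if (object@nLabelled > length(object@fHat))
    return("nLabelled exceeds score count")
  if (any(!is.finite(object@fHat))) return("scores must be finite")
  TRUE
})

#' CausalGraph: estimated directed causal graph
#'
#' Directed graph over the variable set; an edge (i, j) asserts that i has a
#' causal influence on j under the recorded semantics (ancestral or direct).
#' Cycles are permitted. Each edge carries the real-valued classifier score
#' (or the known label for edges supplied as background knowledge).
#'
#' @slot vertices character vector of variable names.
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{score}, \code{labelled}.
#' @slot semantics character: \code{"ancestral"}, \code{"direct"} or
#'   \code{"unspecified"}; inherited from the label source, never altered by
#'   computation.
#'
#' @seealso [runMRCL()], [adjacency()]
#' @export
setClass("CausalGraph",
  slots = c(vertices = "character", edges = "data.frame",
            semantics = "character"))

setValidity("CausalGraph", function(object) {
  need <- c("source", "target", "score", "labelled")
  if (!all(need %in% names(object@edges)))
    return("edges must have columns source, target, score, labelled")
  if (!all(object@edges$source %in% object@vertices) ||
      !all(object@edges$target %in% object@vertices))
    return("edge endpoints must be listed vertices")
  TRUE
})

#' MRCLResult: full output of the MRCL estimator
#'
#' Scores and predicted labels for every pair, the assembled directed graph,
#' the estimated length scale, and solver diagnostics; reproducible from the
#' configuration and seed echoed in \code{config}.
#'
#' @slot scores data.frame, one row per pair: \code{source}, \code{target},
#'   \code{k}, \code{score}, \code{predictedLabel}, \code{labelled}.
#' @slot graph [CausalGraph-class].
#' @slot sigma1 numeric length scale used.
#' @slot config list echoing the configuration.
#' @slot diagnostics list of solver diagnostics.
#'
#' @seealso [runMRCL()]
#' @export
setClass("MRCLResult",
  slots = c(scores = "data.frame", graph = "CausalGraph",
            sigma1 = "numeric", config = "list", diagnostics = "list"))

#' SEMSpec: linear structural-equation system
#'
#' Weight matrix B with \code{B[i, j]} the direct effect of variable i on
#' variable j, independent Gaussian noise scales, and a stability guarantee
#' (spectral radius of B strictly below one) so that cyclic systems have a
#' well-defined equilibrium.
#'
#' @slot B numeric \code{p x p} weight matrix, zero diagonal.
#' @slot noiseScale numeric length-p positive noise standard deviations.
#' @slot cyclic logical, whether cycles were permitted when sampling.
#' @slot seed integer seed used to draw the system.
#'
#' @seealso [sampleSEMSpec()], [simulateObservational()]
#' @export
setClass("SEMSpec",
  slots = c(B = "matrix", noiseScale = "numeric", cyclic = "logical",
            seed = "integer"))

setValidity("SEMSpec", function(object) {
  p <- nrow(object@B)
  if (ncol(object@B) != p) return("B must be square")
  if (any(diag(object@B) != 0)) return("B must have zero diagonal")
  if (length(object@noiseScale) != p)
    return("noiseScale length must equal p")
  if (any(object@noiseScale <= 0)) return("noise scales must be positive")
  rho <- max(Mod(eigen(object@B, only.values = TRUE)$values))
  if (rho >= 1) return(sprintf("unstable system: spectral radius %.3f", rho))
  TRUE
})

#' SyntheticSystem: simulated knockout study
#'
#' A sampled structural-equation system together with observational samples,
#' a single-replicate knockout panel (one interventional measurement of each
#' variable under a hard clamp of each target, emulating a gene-deletion
#' compendium), and the direct and ancestral ground-truth adjacencies.
#'
#' @slot spec [SEMSpec-class].
#' @slot observational numeric matrix, samples x variables.
#' @slot interventionPanel numeric \code{p x p} matrix; row i holds the
#'   measurements of all variables in the experiment clamping variable i.
#' @slot clampValue numeric value targets are clamped to.
#' @slot truthDirect binary \code{p x p} matrix (nonzero direct effects).
#' @slot truthAncestral binary \code{p x p} matrix (total effects above the
#'   relevance threshold, always including direct edges).
#'
#' @seealso [simulateSystem()], [goldStandard()]
#' @export
setClass("SyntheticSystem",
  slots = c(spec = "SEMSpec", observational = "matrix",
            interventionPanel = "matrix", clampValue = "numeric",
            truthDirect = "matrix", truthAncestral = "matrix"))

setValidity("SyntheticSystem", function(object) {
  if (any(object@truthAncestral < object@truthDirect))
    return("ancestral truth must contain every direct edge")
  if (any(diag(object@truthDirect) != 0) ||
      any(diag(object@truthAncestral) != 0))
    return("truth matrices must have zero diagonal")
  TRUE
})

#' GoldStandard: interventional causal reference
#'
#' Robust z-scores of post-intervention change relative to observational
#' variability, and the binary adjacency obtained by strict thresholding
#' (an edge iff zeta > tau). The observational samples are split in half at
#' random: one half provides the medians and IQRs, the other is reserved as
#' training data and exposed through \code{trainIdx}.
#'
#' @slot zeta numeric \code{p x p} matrix of robust z-scores.
#' @slot adjacency binary \code{p x p} matrix, \code{zeta > tau}.
#' @slot tau numeric threshold.
#' @slot splitSeed integer seed of the observational half-split.
#' @slot medians numeric per-variable observational medians.
#' @slot iqrs numeric per-variable observational inter-quartile ranges.
#' @slot trainIdx integer indices of observational samples NOT used for the
#'   medians/IQRs (reserved as training data).
#'
#' @seealso [goldStandard()]
#' @export
setClass("GoldStandard",
  slots = c(zeta = "matrix", adjacency = "matrix", tau = "numeric",
            splitSeed = "integer", medians = "numeric", iqrs = "numeric",
            trainIdx = "integer"))

setValidity("GoldStandard", function(object) {
  if (any(object@zeta < 0)) return("zeta scores must be non-negative")
  offDiag <- row(object@zeta) != col(object@zeta)
  if (!identical(as.logical(object@adjacency[offDiag] != 0),
                 as.vector(object@zeta[offDiag] > object@tau)))
    return("adjacency must equal (zeta > tau) off the diagonal")
  TRUE
})

#' EvalResult: ROC/AUC evaluation of edge scores
#'
#' @slot auc numeric in [0, 1], midrank Mann-Whitney AUC (equals the
#'   trapezoidal area under the ROC curve).
#' @slot roc data.frame with columns \code{fpr}, \code{tpr}, from (0, 0)
#'   to (1, 1), monotone in both coordinates.
#' @slot testSet integer indices of the pairs evaluated.
#' @slot design character, \code{"random"}, \code{"rowwise"} or
#'   \code{"custom"}.
#' @slot rho numeric label fraction of the design (NA when not applicable).
#'
#' @seealso [rocAuc()]
#' @export
setClass("EvalResult",
  slots = c(auc = "numeric", roc = "data.frame", testSet = "integer",
            design = "character", rho = "numeric"))

setValidity("EvalResult", function(object) {
  r <- object@roc
  if (!all(c("fpr", "tpr") %in% names(r)))
    return("roc must have columns fpr and tpr")
  if (nrow(r) < 2 || any(diff(r$fpr) < -1e-12) || any(diff(r$tpr) < -1e-12))
    return("ROC must be monotone non-decreasing")
  if (abs(r$fpr[1]) > 1e-12 || abs(r$tpr[1]) > 1e-12 ||
      abs(r$fpr[nrow(r)] - 1) > 1e-12 || abs(r$tpr[nrow(r)] - 1) > 1e-12)
    return("ROC must run from (0,0) to (1,1)")
  if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
    return("auc must lie in [0, 1]")
  TRUE
})
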