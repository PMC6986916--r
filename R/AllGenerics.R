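#' Accessors for mrcl classes
#'
#' Small accessor generics so that user code never reaches into slots:
#' \code{npairs} (number of ordered pairs), \code{pairIndex}, \code{pairs}
#' \code{pairMatrix} (the (source, target) index matrix), \code{variableNames},
#' \code{pairFeatures} (the feature matrix), \code{similarity},
#' \code{laplacian} (normalized by default), \code{fittedScores},
#' \code{edgeScores}, \code{causalGraph}, \code{adjacency}, \code{zetaScores},
#' \code{aucValue}, \code{rocPoints}, \code{semWeights}, \code{truthDirect}
#' and \code{truthAncestral}.
#'
#' @param object an mrcl S4 object.
#' @param ... passed to methods.
#' @return The requested component; see the class documentation pages.
#' @name mrcl-accessors
#' @examples
#' pi3 <- buildPairIndex(3)
#' npairs(pi3)
#' pairMatrix(pi3)[1:3, ]
NULL

#' @rdname mrcl-accessors
#' @export
setGeneric("npairs", function(object) standardGeneric("npairs"))
#' @rdname mrcl-accessors
#' @export
setGeneric("pairIndex", function(object) standardGeneric("pairIndex"))
#' @rdname mrcl-accessors
#' @export
setGeneric("pairMatrix", function(object) standardGeneric("pairMatrix"))
#' @rdname mrcl-accessors
#' @export
setGeneric("variableNames", function(object) standardGeneric("variableNames"))
#' @rdname mrcl-accessors
#' @export
setGeneric("pairFeatures", function(object) standardGeneric("pairFeatures"))
#' @rdname mrcl-accessors
#' @export
setGeneric("similarity", function(object) standardGeneric("similarity"))
#' @rdname mrcl-accessors
#' @param normalized logical; return the normalized Laplacian?
#' @export
setGeneric("laplacian",
           function(object, normalized = TRUE) standardGeneric("laplacian"))
#' @rdname mrcl-accessors
#' @export
setGeneric("fittedScores", function(object, ...) standardGeneric("fittedScores"))
#' @rdname mrcl-accessors
#' @export
setGeneric("edgeScores", function(object) standardGeneric("edgeScores"))
#' @rdname mrcl-accessors
#' @export
setGeneric("causalGraph", function(object) standardGeneric("causalGraph"))
#' @rdname mrcl-accessors
#' @export
setGeneric("adjacency", function(object, ...) standardGeneric("adjacency"))
#' @rdname mrcl-accessors
#' @export
setGeneric("zetaScores", function(object) standardGeneric("zetaScores"))
#' @rdname mrcl-accessors
#' @export
setGeneric("aucValue", function(object) standardGeneric("aucValue"))
#' @rdname mrcl-accessors
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
#' @rdname mrcl-accessors
#' @export
setGeneric("semWeights", function(object) standardGeneric("semWeights"))
#' @rdname mrcl-accessors
#' @export
setGeneric("truthDirect", function(object) standardGeneric("truthDirect"))
#' @rdname mrcl-accessors
#' @export
setGeneric("truthAncestral", function(object) standardGeneric("truthAncestral"))

## ---- PairIndex ----

#' @rdname mrcl-accessors
#' @export
setMethod("npairs", "PairIndex", function(object) nrow(object@pairs))
#' @rdname mrcl-accessors
#' @export
setMethod("pairMatrix", "PairIndex", function(object) object@pairs)
#' @rdname mrcl-accessors
#' @export
setMethod("variableNames", "PairIndex", function(object) object@varNames)

setMethod("show", "PairIndex", function(object) {
  cat(sprintf("PairIndex: p = %d variables, m = %d ordered pairs (%s diagonal)\n",
              object@p, npairs(object),
              if (object@includeDiagonal) "with" else "without"))
})

## ---- PartialLabels ----

#' @rdname mrcl-accessors
#' @export
setGeneric("labelledPairs", function(object) standardGeneric("labelledPairs"))
#' @rdname mrcl-accessors
#' @export
setGeneric("unlabelledPairs", function(object) standardGeneric("unlabelledPairs"))
#' @rdname mrcl-accessors
#' @export
setGeneric("trainingLabels", function(object) standardGeneric("trainingLabels"))
#' @rdname mrcl-accessors
#' @export
setGeneric("semantics", function(object) standardGeneric("semantics"))

#' @rdname mrcl-accessors
#' @export
setMethod("labelledPairs", "PartialLabels", function(object) object@labelled)
#' @rdname mrcl-accessors
#' @export
setMethod("unlabelledPairs", "PartialLabels",
          function(object) setdiff(seq_len(object@nPairs), object@labelled))
#' @rdname mrcl-accessors
#' @export
setMethod("trainingLabels", "PartialLabels", function(object) object@y)
#' @rdname mrcl-accessors
#' @export
setMethod("semantics", "PartialLabels", function(object) object@semantics)
#' @rdname mrcl-accessors
#' @export
setMethod("npairs", "PartialLabels", function(object) object@nPairs)

setMethod("show", "PartialLabels", function(object) {
  cat(sprintf(
    "PartialLabels: %d labelled (%d positive), %d unlabelled of %d pairs [%s]\n",
    length(object@labelled), sum(object@y > 0),
    object@nPairs - length(object@labelled), object@nPairs,
    object@semantics))
})

## ---- HistogramDensity ----

#' @rdname mrcl-accessors
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))
#' @rdname mrcl-accessors
#' @export
setGeneric("densityValues", function(object) standardGeneric("densityValues"))

#' @rdname mrcl-accessors
#' @export
setMethod("binCounts", "HistogramDensity", function(object) object@counts)

#' @rdname mrcl-accessors
#' @export
setMethod("densityValues", "HistogramDensity", function(object) {
  object@counts / (object@nPoints * object@binWidth^2)
})

setMethod("show", "HistogramDensity", function(object) {
  cat(sprintf("HistogramDensity: %d x %d bins (width %.3g) on [%g, %g]^2, n = %d\n",
              object@bins, object@bins, object@binWidth,
              object@bounds[1], object@bounds[2], object@nPoints))
})

## ---- PairFeatureMatrix ----

#' @rdname mrcl-accessors
#' @export
setMethod("pairFeatures", "PairFeatureMatrix", function(object) object@features)
#' @rdname mrcl-accessors
#' @export
setMethod("pairIndex", "PairFeatureMatrix", function(object) object@pairIndex)
#' @rdname mrcl-accessors
#' @export
setMethod("npairs", "PairFeatureMatrix", function(object) nrow(object@features))

#' @rdname mrcl-accessors
#' @export
setGeneric("featureStage", function(object) standardGeneric("featureStage"))
#' @rdname mrcl-accessors
#' @export
setMethod("featureStage", "PairFeatureMatrix", function(object) object@stage)

setMethod("show", "PairFeatureMatrix", function(object) {
  cat(sprintf("PairFeatureMatrix: %d pairs x %d features [%s stage], n = %d per scatter\n",
              nrow(object@features), ncol(object@features), object@stage,
              object@nPoints))
})

## ---- ManifoldGraph ----

#' @rdname mrcl-accessors
#' @export
setMethod("similarity", "ManifoldGraph", function(object) object@W)
#' @rdname mrcl-accessors
#' @export
setMethod("laplacian", "ManifoldGraph", function(object, normalized = TRUE) {
  if (normalized) object@laplacianNorm else object@laplacian
})

#' @rdname mrcl-accessors
#' @export
setGeneric("lengthScale", function(object) standardGeneric("lengthScale"))
#' @rdname mrcl-accessors
#' @export
setMethod("lengthScale", "ManifoldGraph", function(object) object@sigma1)

setMethod("show", "ManifoldGraph", function(object) {
  cat(sprintf("ManifoldGraph: %d nodes, sigma1 = %.4g, mean degree %.3g\n",
              nrow(object@W), object@sigma1, mean(object@degrees)))
})

## ---- KernelMatrix ----

#' @rdname mrcl-accessors
#' @export
setGeneric("kernelValues", function(object) standardGeneric("kernelValues"))
#' @rdname mrcl-accessors
#' @export
setMethod("kernelValues", "KernelMatrix", function(object) object@K)

setMethod("show", "KernelMatrix", function(object) {
  cat(sprintf("KernelMatrix: %d x %d, sigma2 = %.4g, nLabelled = %s\n",
              nrow(object@K), ncol(object@K), object@sigma2,
              if (length(object@nLabelled)) object@nLabelled else "unset"))
})

## ---- LapRLSFit ----

#' @rdname mrcl-accessors
#' @param which one of "all", "labelled", "unlabelled".
#' @export
setMethod("fittedScores", "LapRLSFit", function(object, which = c("all", "labelled", "unlabelled")) {
  which <- match.arg(which)
  mL <- object@nLabelled
  switch(which,
         all = object@fHat,
         labelled = object@fHat[seq_len(mL)],
         unlabelled = if (mL < length(object@fHat))
           object@fHat[(mL + 1L):length(object@fHat)] else numeric(0))
})

setMethod("show", "LapRLSFit", function(object) {
  cat(sprintf(
    "LapRLSFit: %d pairs (%d labelled), lambda1 = %g, lambda2 = %g, residual %.2e\n",
    length(object@fHat), object@nLabelled, object@lambda1, object@lambda2,
    object@diagnostics$residual))
})

## ---- CausalGraph ----

#' @rdname mrcl-accessors
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))
#' @rdname mrcl-accessors
#' @export
setMethod("edges", "CausalGraph", function(object) object@edges)
#' @rdname mrcl-accessors
#' @export
setMethod("variableNames", "CausalGraph", function(object) object@vertices)
#' @rdname mrcl-accessors
#' @export
setMethod("semantics", "CausalGraph", function(object) object@semantics)

#' @rdname mrcl-accessors
#' @export
setMethod("adjacency", "CausalGraph", function(object, ...) {
  p <- length(object@vertices)
  A <- matrix(0L, p, p, dimnames = list(object@vertices, object@vertices))
  if (nrow(object@edges))
    A[cbind(match(object@edges$source, object@vertices),
            match(object@edges$target, object@vertices))] <- 1L
  A
})

setMethod("show", "CausalGraph", function(object) {
  cat(sprintf("CausalGraph (%s semantics): %d vertices, %d directed edges\n",
              object@semantics, length(object@vertices), nrow(object@edges)))
})

## ---- MRCLResult ----

#' @rdname mrcl-accessors
#' @export
setMethod("edgeScores", "MRCLResult", function(object) object@scores)
#' @rdname mrcl-accessors
#' @export
setMethod("causalGraph", "MRCLResult", function(object) object@graph)
#' @rdname mrcl-accessors
#' @export
setMethod("lengthScale", "MRCLResult", function(object) object@sigma1)

setMethod("show", "MRCLResult", function(object) {
  nU <- sum(!object@scores$labelled)
  cat(sprintf(
    "MRCLResult: %d pairs scored (%d unlabelled), sigma1 = %.4g\n",
    nrow(object@scores), nU, object@sigma1))
  show(object@graph)
})

## ---- SEMSpec / SyntheticSystem ----

#' @rdname mrcl-accessors
#' @export
setMethod("semWeights", "SEMSpec", function(object) object@B)

setMethod("show", "SEMSpec", function(object) {
  cat(sprintf("SEMSpec: p = %d, %d edges, %s, spectral radius %.3f\n",
              nrow(object@B), sum(object@B != 0),
              if (object@cyclic) "cyclic allowed" else "acyclic",
              max(Mod(eigen(object@B, only.values = TRUE)$values))))
})

#' @rdname mrcl-accessors
#' @export
setMethod("truthDirect", "SyntheticSystem", function(object) object@truthDirect)
#' @rdname mrcl-accessors
#' @export
setMethod("truthAncestral", "SyntheticSystem", function(object) object@truthAncestral)
#' @rdname mrcl-accessors
#' @export
setMethod("semWeights", "SyntheticSystem", function(object) object@spec@B)

setMethod("show", "SyntheticSystem", function(object) {
  cat(sprintf(
    "SyntheticSystem: p = %d, %d obs samples, knockout panel (clamp %g), %d/%d direct/ancestral edges\n",
    nrow(object@spec@B), nrow(object@observational), object@clampValue,
    sum(object@truthDirect), sum(object@truthAncestral)))
})

## ---- GoldStandard / EvalResult ----

#' @rdname mrcl-accessors
#' @export
setMethod("zetaScores", "GoldStandard", function(object) object@zeta)
#' @rdname mrcl-accessors
#' @export
setMethod("adjacency", "GoldStandard", function(object, ...) object@adjacency)

#' @rdname mrcl-accessors
#' @export
setGeneric("trainingIndices", function(object) standardGeneric("trainingIndices"))
#' @rdname mrcl-accessors
#' @export
setMethod("trainingIndices", "GoldStandard", function(object) object@trainIdx)

setMethod("show", "GoldStandard", function(object) {
  cat(sprintf("GoldStandard: %d x %d, tau = %g, %d edges (%.1f%% of off-diagonal pairs)\n",
              nrow(object@zeta), ncol(object@zeta), object@tau,
              sum(object@adjacency),
              100 * sum(object@adjacency) /
                (nrow(object@zeta) * (nrow(object@zeta) - 1))))
})

#' @rdname mrcl-accessors
#' @export
setMethod("aucValue", "EvalResult", function(object) object@auc)
#' @rdname mrcl-accessors
#' @export
setMethod("rocPoints", "EvalResult", function(object) object@roc)

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult: AUC = %.4f on %d test pairs [%s design%s]\n",
              object@auc, length(object@testSet), object@design,
              if (is.na(object@rho)) "" else sprintf(", rho = %g", object@rho)))
})
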