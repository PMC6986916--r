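## Bivariate-histogram featurization of variable pairs.
##
## Every ordered pair (i, j) of variables is represented by the bin counts of
## the scatter plot of the standardized, truncated samples (z_i, z_j) on a
## regular M x M grid. The Euclidean distance between two count vectors is
## proportional to the L2 distance between the corresponding histogram
## density estimates whenever the sample size and grid are shared, which is
## enforced by construction here (truncation clips rather than drops
## samples, so every scatter plot has exactly n points).

#' Standardize and truncate a data matrix
#'
#' Z-scores every column by its own sample mean and standard deviation, then
#' clips (winsorizes) values to the given bounds so that every sample lies in
#' the square domain used for histogram binning. Clipping rather than sample
#' removal keeps the number of points identical across variable pairs, which
#' in turn keeps histogram count vectors directly comparable.
#'
#' @param data numeric matrix, samples in rows, variables in columns
#'   (column names are the variable names).
#' @param bounds numeric length-2, the truncation interval per axis
#'   (default \code{c(-3, 3)}).
#' @return A numeric matrix of the same shape, each column with (pre-clip)
#'   mean 0 and standard deviation 1, all values within \code{bounds}.
#' @examples
#' x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
#' z <- standardizeTruncate(x)
#' range(z)
#' @export
standardizeTruncate <- function(data, bounds = c(-3, 3)) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (nrow(data) < 2 || ncol(data) < 2)
    stop("need at least 2 samples and 2 variables")
  if (length(bounds) != 2 || bounds[1] >= bounds[2])
    stop("bounds must be an increasing length-2 interval")
  if (anyNA(data)) {
    idx <- which(is.na(data), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column %s", idx[1],
                 colnames(data)[idx[2]] %||% idx[2]))
  }
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    stop(sprintf("zero-variance column: %s",
                 colnames(data)[bad] %||% bad))
  }
  z <- scale(data, center = TRUE, scale = TRUE)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z[z < bounds[1]] <- bounds[1]
  z[z > bounds[2]] <- bounds[2]
  attr(z, "bounds") <- bounds
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the scatter plot of an ordered variable pair
#'
#' Returns the n points \code{(z_i, z_j)}, the sample of the bivariate
#' marginal of the ordered pair. Ordered-pair semantics: swapping i and j
#' transposes the coordinates, so \code{(i, j)} and \code{(j, i)} yield
#' distinct (coordinate-swapped) scatter plots.
#'
#' @param data standardized, truncated data matrix
#'   (see [standardizeTruncate()]).
#' @param i,j variable (column) indices or names.
#' @return numeric n x 2 matrix of points.
#' @examples
#' z <- standardizeTruncate(matrix(rnorm(100), 25, 4))
#' s <- extractScatter(z, 1, 2)
#' all(s == extractScatter(z, 2, 1)[, 2:1])
#' @export
extractScatter <- function(data, i, j) {
  if (is.character(i)) i <- match(i, colnames(data))
  if (is.character(j)) j <- match(j, colnames(data))
  p <- ncol(data)
  if (is.na(i) || is.na(j) || i < 1 || j < 1 || i > p || j > p)
    stop("variable index out of range")
  cbind(data[, i], data[, j])
}

## Map coordinates to bin indices on a regular grid: half-open bins
## [a, b) except the last, which is closed so the upper boundary is counted.
binIndices <- function(v, bounds, M) {
  h <- diff(bounds) / M
  idx <- floor((v - bounds[1]) / h) + 1
  idx[idx > M] <- M
  idx[v == bounds[2]] <- M
  as.integer(idx)
}

#' Bivariate histogram density estimate of a scatter plot
#'
#' Counts points on the regular \code{M x M} grid over the square domain.
#' Bins are half-open \code{[a, b)} except the last along each axis, which is
#' closed so that points exactly on the upper boundary (produced by
#' truncation) are counted. The density estimate on a bin with count x is
#' \code{x / (n h^2)} and integrates to one over the domain.
#'
#' @param s n x 2 matrix of points (see [extractScatter()]); all points must
#'   lie within \code{bounds} (truncate first).
#' @param bins integer M, bins per axis (default 30, i.e. bin width 0.2 on
#'   \code{[-3, 3]}).
#' @param bounds numeric length-2 domain bounds (default \code{c(-3, 3)}).
#' @return A [HistogramDensity-class] object.
#' @examples
#' s <- matrix(runif(60, -3, 3), 30, 2)
#' hd <- histogramDensity(s)
#' sum(binCounts(hd)) == nrow(s)
#' @export
histogramDensity <- function(s, bins = 30L, bounds = c(-3, 3)) {
  s <- as.matrix(s)
  if (ncol(s) != 2) stop("scatter plot must have two columns")
  bins <- as.integer(bins)
  if (bins < 1) stop("bins must be >= 1")
  if (any(s < bounds[1]) || any(s > bounds[2]))
    stop("point outside bounds: truncation must precede binning")
  ix <- binIndices(s[, 1], bounds, bins)
  iy <- binIndices(s[, 2], bounds, bins)
  counts <- matrix(tabulate((ix - 1L) * bins + iy, nbins = bins * bins),
                   nrow = bins, ncol = bins, byrow = TRUE)
  new("HistogramDensity", counts = counts, bins = bins,
      binWidth = diff(bounds) / bins, bounds = as.numeric(bounds),
      nPoints = nrow(s))
}

#' L2 distance between two histogram density estimates
#'
#' The L2(Lebesgue) distance between the piecewise-constant density
#' estimates, computed from the bin counts:
#' \code{||c1/(n1 h^2) - c2/(n2 h^2)|| * h}. Requires a shared grid. This is
#' the sample analogue of the L2 distance between the underlying bivariate
#' densities; it is a pseudo-metric on scatter plots (symmetric, zero on
#' identical inputs, triangle inequality), and when the two scatter plots
#' share the sample size n it is proportional to the Euclidean distance
#' between the raw count vectors used as classifier features.
#'
#' @param a,b [HistogramDensity-class] objects on the same grid.
#' @return non-negative numeric distance.
#' @examples
#' s <- matrix(runif(60, -3, 3), 30, 2)
#' histogramDistance(histogramDensity(s), histogramDensity(s)) == 0
#' @export
histogramDistance <- function(a, b) {
  stopifnot(is(a, "HistogramDensity"), is(b, "HistogramDensity"))
  if (a@bins != b@bins || any(a@bounds != b@bounds))
    stop("histograms must share the same grid")
  da <- a@counts / (a@nPoints * a@binWidth^2)
  db <- b@counts / (b@nPoints * b@binWidth^2)
  sqrt(sum((da - db)^2)) * a@binWidth
}

#' Histogram features for all ordered variable pairs
#'
#' Builds the raw-stage feature matrix: row k is the vectorized bin-count
#' grid of the scatter plot of pair \code{(i[k], j[k])}. Vectorization is
#' row-major in the grid: feature column \code{(m1 - 1) * M + m2} holds the
#' count of bin \code{(m1, m2)}, where m1 bins the source variable and m2
#' the target. Deterministic given inputs.
#'
#' @param data standardized, truncated data matrix.
#' @param pairs a [PairIndex-class] over the columns of \code{data}
#'   (default: all ordered non-diagonal pairs).
#' @param bins integer M, bins per axis (default 30).
#' @param bounds numeric length-2 domain bounds (default \code{c(-3, 3)}).
#' @return A raw-stage [PairFeatureMatrix-class]; every row sums to n.
#' @examples
#' z <- standardizeTruncate(matrix(rnorm(150), 50, 3))
#' f <- featurizePairs(z)
#' dim(pairFeatures(f))
#' @export
featurizePairs <- function(data, pairs = NULL, bins = 30L, bounds = c(-3, 3)) {
  data <- as.matrix(data)
  if (is.null(pairs)) pairs <- buildPairIndex(ncol(data),
                                              varNames = colnames(data))
  stopifnot(is(pairs, "PairIndex"))
  if (pairs@p != ncol(data))
    stop("pair index does not match the number of variables")
  bins <- as.integer(bins)
  if (any(data < bounds[1]) || any(data > bounds[2]))
    stop("data outside bounds: run standardizeTruncate first")
  n <- nrow(data)
  idx <- vapply(seq_len(ncol(data)),
                function(jj) binIndices(data[, jj], bounds, bins),
                integer(n))
  pm <- pairs@pairs
  m <- nrow(pm)
  feats <- matrix(0, m, bins * bins)
  for (k in seq_len(m)) {
    ## row-major vectorized counts: source variable indexes the M-blocks
    feats[k, ] <- tabulate((idx[, pm[k, 1]] - 1L) * bins + idx[, pm[k, 2]],
                           nbins = bins * bins)
  }
  new("PairFeatureMatrix", features = feats, pairIndex = pairs,
      stage = "raw", nPoints = as.integer(n), bins = bins,
      bounds = as.numeric(bounds), center = numeric(0),
      rotation = matrix(0, 0, 0))
}

#' Reduce feature dimension by PCA
#'
#' Mean-centers the raw count features and projects onto the leading
#' principal components, ordered by decreasing explained variance. At most
#' \code{min(targetDim, m, M^2)} components are retained. The PCA is fitted
#' jointly on all pairs (labelled and unlabelled), consistent with the
#' transductive classifier. Component signs are fixed by making the
#' largest-magnitude loading of each component positive, so output is
#' reproducible. When no components are discarded the projection is a
#' rotation, so all pairwise Euclidean distances are preserved.
#'
#' @param feats raw-stage [PairFeatureMatrix-class].
#' @param targetDim positive integer, number of components to retain
#'   (default 100).
#' @return A pca-stage [PairFeatureMatrix-class] carrying the centering
#'   vector and loadings.
#' @examples
#' z <- standardizeTruncate(matrix(rnorm(300), 100, 3))
#' f <- reduceDimension(featurizePairs(z), 4)
#' ncol(pairFeatures(f))
#' @export
reduceDimension <- function(feats, targetDim = 100L) {
  stopifnot(is(feats, "PairFeatureMatrix"))
  if (feats@stage != "raw") stop("features must be at the raw stage")
  targetDim <- as.integer(targetDim)
  if (targetDim < 1) stop("targetDim must be >= 1")
  X <- feats@features
  d <- min(targetDim, nrow(X), ncol(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  d <- min(d, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  ## sign convention: largest-magnitude loading positive
  flip <- vapply(seq_len(d), function(jj) {
    v <- rot[, jj]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(X, 2, pc$center) %*% rot
  new("PairFeatureMatrix", features = unname(scores),
      pairIndex = feats@pairIndex, stage = "pca",
      nPoints = feats@nPoints, bins = feats@bins, bounds = feats@bounds,
      center = pc$center, rotation = rot)
}
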