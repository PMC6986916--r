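## Similarity graph, Laplacians and kernel over variable-pair features.

#' Estimate the similarity length scale from the feature cloud
#'
#' The length scale is set to the average distance to the nearest
#' \code{kNeighbors} points in feature space: for each of up to
#' \code{subsampleSize} uniformly sampled rows (seeded), Euclidean distances
#' to all other rows are computed, the smallest \code{min(kNeighbors, m-1)}
#' are averaged (self-distance excluded), and the result is averaged over
#' the subsample. When the feature cloud is degenerate (all rows identical)
#' no scale exists and an error asks the caller to supply sigma explicitly.
#'
#' @param feats [PairFeatureMatrix-class] or numeric matrix of features.
#' @param kNeighbors positive integer, neighbours averaged (default 50).
#' @param subsampleSize positive integer, rows sampled for the estimate
#'   (default 1000).
#' @param seed integer seed for the subsample (default 1).
#' @return positive numeric length scale.
#' @examples
#' estimateLengthScale(matrix(rnorm(60), 20, 3), kNeighbors = 3)
#' @export
estimateLengthScale <- function(feats, kNeighbors = 50L,
                                subsampleSize = 1000L, seed = 1L) {
  X <- if (is(feats, "PairFeatureMatrix")) feats@features else as.matrix(feats)
  m <- nrow(X)
  if (m < 2) stop("need at least two feature rows")
  if (kNeighbors < 1 || subsampleSize < 1)
    stop("kNeighbors and subsampleSize must be positive")
  k <- min(as.integer(kNeighbors), m - 1L)
  rows <- if (subsampleSize >= m) seq_len(m) else
    withSeed(seed, sort(sample.int(m, subsampleSize)))
  sq <- rowSums(X^2)
  perRow <- vapply(rows, function(r) {
    d2 <- sq + sq[r] - 2 * drop(X %*% X[r, ])
    d2[r] <- Inf
    d2[d2 < 0] <- 0
    mean(sqrt(sort(d2, partial = k)[seq_len(k)]))
  }, numeric(1))
  sigma <- mean(perRow)
  if (sigma == 0)
    stop("all feature rows are identical; supply sigma explicitly")
  sigma
}

#' Squared-exponential similarity matrix
#'
#' \code{W[k, k'] = exp(-||x_k - x_k'||^2 / (2 sigma1^2))}: symmetric, unit
#' diagonal, entries in (0, 1], non-increasing in the feature distance and
#' non-decreasing in \code{sigma1}.
#'
#' @param feats [PairFeatureMatrix-class] or numeric feature matrix.
#' @param sigma1 positive length scale.
#' @return numeric m x m similarity matrix.
#' @examples
#' W <- similarityMatrix(matrix(rnorm(20), 5, 4), sigma1 = 2)
#' diag(W)
#' @export
similarityMatrix <- function(feats, sigma1) {
  X <- if (is(feats, "PairFeatureMatrix")) feats@features else as.matrix(feats)
  if (!is.numeric(sigma1) || length(sigma1) != 1 || sigma1 <= 0)
    stop("sigma1 must be a positive scalar")
  if (any(!is.finite(X))) stop("non-finite feature values")
  W <- exp(-squaredDistances(X) / (2 * sigma1^2))
  W <- (W + t(W)) / 2
  diag(W) <- 1
  W
}

#' Graph Laplacian of a similarity matrix
#'
#' Returns \code{L = D - W} with \code{D} the diagonal degree matrix, or the
#' normalized form \code{D^{-1/2} L D^{-1/2}} when \code{normalized} is set.
#' L has zero row sums and is positive semi-definite; the normalized form
#' has eigenvalues in [0, 2]. Degrees are floored at a tiny positive value
#' before the inverse square root to guard against underflow when distances
#' are huge relative to the length scale.
#'
#' @param W symmetric non-negative similarity matrix.
#' @param normalized logical (default \code{FALSE}).
#' @param tol symmetry tolerance (default 1e-8).
#' @return numeric m x m Laplacian.
#' @examples
#' W <- similarityMatrix(matrix(rnorm(20), 5, 4), sigma1 = 2)
#' rowSums(graphLaplacian(W))
#' @export
graphLaplacian <- function(W, normalized = FALSE, tol = 1e-8) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (max(abs(W - t(W))) > tol) stop("W is not symmetric within tolerance")
  if (any(W < 0)) stop("W must be non-negative")
  deg <- rowSums(W)
  L <- -W
  diag(L) <- diag(L) + deg
  if (!normalized) return(L)
  dinv <- 1 / sqrt(pmax(deg, 1e-300))
  Ln <- L * outer(dinv, dinv)
  (Ln + t(Ln)) / 2
}

#' Build the full manifold graph over pair features
#'
#' Convenience constructor assembling the similarity matrix, degrees, and
#' both Laplacians for a given (or estimated) length scale.
#'
#' @param feats [PairFeatureMatrix-class] or numeric feature matrix.
#' @param sigma1 positive length scale, or \code{NULL} to estimate it via
#'   [estimateLengthScale()].
#' @param kNeighbors,subsampleSize,seed passed to [estimateLengthScale()]
#'   when \code{sigma1} is \code{NULL}.
#' @return A [ManifoldGraph-class] object.
#' @examples
#' g <- manifoldGraph(matrix(rnorm(60), 20, 3), sigma1 = 1.5)
#' range(eigen(laplacian(g), only.values = TRUE)$values)
#' @export
manifoldGraph <- function(feats, sigma1 = NULL, kNeighbors = 50L,
                          subsampleSize = 1000L, seed = 1L) {
  if (is.null(sigma1))
    sigma1 <- estimateLengthScale(feats, kNeighbors, subsampleSize, seed)
  W <- similarityMatrix(feats, sigma1)
  new("ManifoldGraph", W = W, degrees = rowSums(W),
      laplacian = graphLaplacian(W, normalized = FALSE),
      laplacianNorm = graphLaplacian(W, normalized = TRUE),
      sigma1 = sigma1)
}

#' Squared-exponential kernel matrix
#'
#' The Mercer kernel \code{K(x, x') = exp(-||x - x'||^2 / (2 sigma2^2))}
#' evaluated at all pairs of feature rows; by default the kernel length
#' scale equals the similarity length scale, in which case K equals the
#' similarity matrix exactly. Positive semi-definite up to numerical
#' tolerance, unit diagonal.
#'
#' @param feats [PairFeatureMatrix-class] or numeric feature matrix.
#' @param sigma2 positive length scale.
#' @param nLabelled optional integer: number of leading rows that are
#'   labelled pairs (fixes the partition for [fitTransduce()]).
#' @return A [KernelMatrix-class] object.
#' @examples
#' K <- kernelMatrix(matrix(rnorm(20), 5, 4), sigma2 = 2)
#' kernelValues(K)[1, 1]
#' @export
kernelMatrix <- function(feats, sigma2, nLabelled = NA_integer_) {
  K <- similarityMatrix(feats, sigma2)
  new("KernelMatrix", K = K, sigma2 = sigma2,
      nLabelled = as.integer(nLabelled))
}
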