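## Laplacian-regularized least-squares transduction.
##
## The classifier minimizes, over functions f in the RKHS of the kernel K,
##
##   (1/m_L) ||y^L - f^L||^2  +  (lambda1/m^2) f' L f  +  lambda2 ||f||_H^2
##
## whose finite representer form f = K alpha has the closed-form solution
##
##   alpha = (J K + lambda2 m_L I + (lambda1 m_L / m^2) L K)^{-1} [y^L; 0]
##
## with J the diagonal selector of labelled entries. Pairs must be ordered
## with the labelled block first; scores at unlabelled pairs are the output.

#' Fit the transductive classifier in closed form
#'
#' Solves the Laplacian-regularized least-squares problem over the fixed set
#' of m pairs, labelled pairs first. The (generally non-symmetric) linear
#' system is solved by a dense LU solve (not explicit inversion); the
#' relative residual and a condition estimate are recorded and an
#' ill-conditioned solve beyond tolerance is an error.
#'
#' @param kernel [KernelMatrix-class] over all m pairs (labelled block
#'   first).
#' @param laplacian m x m graph Laplacian (the normalized Laplacian by
#'   default in [runMRCL()]; any PSD smoothness matrix is accepted here).
#' @param yLabels numeric vector of m_L labels in \{-1, +1\} for the leading
#'   block; \code{m_L >= 1}.
#' @param lambda1 non-negative manifold penalty weight (default 0.001).
#' @param lambda2 positive RKHS-norm penalty weight (default 0.001).
#' @param residTol maximum relative residual of the solve (default 1e-8).
#' @return A [LapRLSFit-class] with scores for all m pairs.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' K <- kernelMatrix(X, sigma2 = 2)
#' L <- graphLaplacian(similarityMatrix(X, 2), normalized = TRUE)
#' fit <- fitTransduce(K, L, yLabels = c(1, -1, 1))
#' fittedScores(fit, "unlabelled")
#' @export
fitTransduce <- function(kernel, laplacian, yLabels, lambda1 = 0.001,
                         lambda2 = 0.001, residTol = 1e-8) {
  stopifnot(is(kernel, "KernelMatrix"))
  K <- kernel@K
  m <- nrow(K)
  mL <- length(yLabels)
  if (mL < 1) stop("at least one labelled pair is required")
  if (mL > m) stop("more labels than pairs")
  if (!all(yLabels %in% c(-1, 1)))
    stop("labels must lie in {-1, +1}")
  if (length(kernel@nLabelled) == 1 && !is.na(kernel@nLabelled) &&
      kernel@nLabelled != mL)
    stop("label count disagrees with the kernel's recorded partition")
  laplacian <- as.matrix(laplacian)
  if (!all(dim(laplacian) == m)) stop("laplacian dimension mismatch")
  if (lambda1 < 0) stop("lambda1 must be non-negative")
  if (lambda2 <= 0) stop("lambda2 must be positive")

  y0 <- c(yLabels, rep(0, m - mL))
  Jdiag <- c(rep(1, mL), rep(0, m - mL))
  A <- Jdiag * K                      # J K: zero out unlabelled rows
  diag(A) <- diag(A) + lambda2 * mL
  A <- A + (lambda1 * mL / m^2) * (laplacian %*% K)
  kap <- kappa(A, exact = FALSE)
  alpha <- tryCatch(solve(A, y0), error = function(e)
    stop(sprintf("singular system (condition estimate %.3g): %s",
                 kap, conditionMessage(e)), call. = FALSE))
  resid <- sqrt(sum((A %*% alpha - y0)^2)) / sqrt(sum(y0^2))
  if (!is.finite(resid) || resid > residTol)
    stop(sprintf(
      "ill-conditioned solve: relative residual %.3g (condition estimate %.3g)",
      resid, kap))
  fHat <- drop(K %*% alpha)
  new("LapRLSFit", fHat = fHat, nLabelled = as.integer(mL),
      yTrain = as.numeric(yLabels), lambda1 = lambda1, lambda2 = lambda2,
      diagnostics = list(residual = resid, conditionEstimate = kap,
                         alpha = alpha))
}

#' Representer-form objective of the transductive fit
#'
#' Evaluates, at coefficients \code{alpha} (with \code{f = K alpha}),
#' \deqn{(1/m_L) ||y^L - f^L||_2^2 + (\lambda_1/m^2) f' L f
#'       + \lambda_2 \alpha' K \alpha.}
#' Used as a test oracle (direct numerical minimization must agree with the
#' closed form) and for diagnostics; the fitting path never calls it.
#'
#' @param alpha numeric length-m coefficient vector.
#' @param kernel [KernelMatrix-class] over all m pairs.
#' @param laplacian m x m smoothness matrix.
#' @param yLabels numeric m_L labels in \{-1, +1\} (leading block).
#' @param lambda1,lambda2 penalty weights as in [fitTransduce()].
#' @return non-negative numeric objective value.
#' @examples
#' K <- kernelMatrix(matrix(rnorm(20), 5, 4), sigma2 = 2)
#' L <- graphLaplacian(kernelValues(K))
#' laprlsObjective(rep(0, 5), K, L, c(1, -1))   # equals 1 at alpha = 0
#' @export
laprlsObjective <- function(alpha, kernel, laplacian, yLabels,
                            lambda1 = 0.001, lambda2 = 0.001) {
  stopifnot(is(kernel, "KernelMatrix"))
  K <- kernel@K
  m <- nrow(K)
  mL <- length(yLabels)
  if (length(alpha) != m) stop("alpha must have length m")
  if (!all(dim(as.matrix(laplacian)) == m))
    stop("laplacian dimension mismatch")
  f <- drop(K %*% alpha)
  sum((yLabels - f[seq_len(mL)])^2) / mL +
    (lambda1 / m^2) * drop(crossprod(f, as.matrix(laplacian) %*% f)) +
    lambda2 * drop(crossprod(alpha, K %*% alpha))
}

#' Sign labels from a fitted classifier
#'
#' \code{+1} iff the score is strictly positive; a score of exactly zero is
#' classified \code{-1} (conservative: no edge). Real-valued scores are kept
#' alongside for ranking.
#'
#' @param fit [LapRLSFit-class].
#' @param which which block to classify: \code{"unlabelled"} (default) or
#'   \code{"all"}.
#' @return numeric vector of labels in \{-1, +1\}.
#' @examples
#' classifyPairs(new("LapRLSFit", fHat = c(0.3, -0.2, 0), nLabelled = 1L,
#'                   yTrain = 1, lambda1 = 0, lambda2 = 1,
#'                   diagnostics = list(residual = 0)))
#' @export
classifyPairs <- function(fit, which = c("unlabelled", "all")) {
  stopifnot(is(fit, "LapRLSFit"))
  which <- match.arg(which)
  f <- fittedScores(fit, which)
  ifelse(f > 0, 1, -1)
}
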