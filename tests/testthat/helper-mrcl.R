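## Shared fixtures and independent oracles for the test suite.

## Random scatter plot within the square domain.
randomScatter <- function(n, bounds = c(-3, 3)) {
  matrix(stats::runif(2 * n, bounds[1], bounds[2]), n, 2)
}

## Random transduction instance: RBF kernel + normalized Laplacian over a
## small random feature cloud, with random +/-1 labels on the leading block.
randomInstance <- function(m = NULL, mL = NULL, d = 5, lambda1 = 0.001,
                           lambda2 = 0.001) {
  if (is.null(m)) m <- sample(6:30, 1)
  if (is.null(mL)) mL <- sample(2:(m - 1), 1)
  X <- matrix(rnorm(m * d), m, d)
  sigma <- sqrt(median(as.matrix(dist(X))^2))
  K <- kernelMatrix(X, sigma2 = sigma)
  W <- similarityMatrix(X, sigma)
  Ln <- graphLaplacian(W, normalized = TRUE)
  y <- sample(c(-1, 1), mL, replace = TRUE)
  if (length(unique(y)) == 1) y[1] <- -y[1]
  list(m = m, mL = mL, K = K, L = Ln, y = y,
       lambda1 = lambda1, lambda2 = lambda2)
}

## Independent minimizer of the representer objective: linear conjugate
## gradient driven only by the objective's gradient (the objective is
## quadratic in alpha, so grad(a) = H a - b with H v = grad(v) - grad(0)).
## Never forms or solves the closed-form linear system.
cgMinimizeObjective <- function(inst, tol = 1e-13, maxit = 50000) {
  gradObj <- function(a) {
    K <- kernelValues(inst$K)
    m <- inst$m; mL <- inst$mL
    y0 <- c(inst$y, rep(0, m - mL))
    Jd <- c(rep(1, mL), rep(0, m - mL))
    f <- drop(K %*% a)
    drop(2 * K %*% (Jd * (f - y0)) / mL +
           (2 * inst$lambda1 / m^2) * K %*% (inst$L %*% f) +
           2 * inst$lambda2 * (K %*% a))
  }
  g0 <- gradObj(rep(0, inst$m))
  b <- -g0
  x <- rep(0, inst$m); r <- b; p <- r; rs <- sum(r * r)
  bn <- sqrt(sum(b * b))
  for (it in seq_len(maxit)) {
    Hp <- gradObj(p) - g0
    alpha <- rs / sum(p * Hp)
    x <- x + alpha * p
    r <- r - alpha * Hp
    rs2 <- sum(r * r)
    if (sqrt(rs2) < tol * bn) break
    p <- r + (rs2 / rs) * p
    rs <- rs2
  }
  x
}

## Closed-form fit of a random instance (the implementation path).
fitInstance <- function(inst) {
  fitTransduce(inst$K, inst$L, inst$y, lambda1 = inst$lambda1,
               lambda2 = inst$lambda2)
}

## Trapezoidal area under an ROC data.frame (independent of the midrank
## statistic the implementation reports).
trapezoidArea <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}
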