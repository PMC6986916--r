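## Numerical experiments validating the density-estimation theory behind
## the featurization: the L2 convergence rate of the bivariate histogram and
## the consistency of the sample distance between scatter plots. Both use a
## fixed pair of smooth (Gaussian-mixture, truncated and renormalized)
## densities on the square domain; true L2 quantities are computed by
## midpoint quadrature on a grid aligned with the histogram bins.

## Fixed smooth test densities on [-3, 3]^2 (twice continuously
## differentiable on the closed square). id = 1 or 2.
mixtureParams <- function(id) {
  if (id == 1)
    list(mu = rbind(c(-1, -0.5), c(1.2, 0.8)),
         sd = rbind(c(1.1, 0.9), c(0.8, 1.2)), w = c(0.45, 0.55))
  else
    list(mu = rbind(c(0.5, -1), c(-1.2, 1.1)),
         sd = rbind(c(0.9, 1.2), c(1.1, 0.7)), w = c(0.5, 0.5))
}

mixtureDensity <- function(x, y, pars) {
  out <- 0
  for (c_ in seq_along(pars$w))
    out <- out + pars$w[c_] *
      stats::dnorm(x, pars$mu[c_, 1], pars$sd[c_, 1]) *
      stats::dnorm(y, pars$mu[c_, 2], pars$sd[c_, 2])
  out
}

## Normalizing constant of the mixture restricted to the square, by the
## product-form Gaussian CDF (exact for axis-aligned components).
mixtureMass <- function(pars, bounds) {
  s <- 0
  for (c_ in seq_along(pars$w)) {
    px <- stats::pnorm(bounds[2], pars$mu[c_, 1], pars$sd[c_, 1]) -
      stats::pnorm(bounds[1], pars$mu[c_, 1], pars$sd[c_, 1])
    py <- stats::pnorm(bounds[2], pars$mu[c_, 2], pars$sd[c_, 2]) -
      stats::pnorm(bounds[1], pars$mu[c_, 2], pars$sd[c_, 2])
    s <- s + pars$w[c_] * px * py
  }
  s
}

#' Sample from a fixed smooth test density
#'
#' Rejection-samples n points from one of two built-in Gaussian-mixture
#' densities truncated to the square domain; used by the rate and
#' consistency experiments.
#'
#' @param n number of points.
#' @param id which density, 1 or 2.
#' @param bounds numeric length-2 square bounds (default \code{c(-3, 3)}).
#' @param seed integer seed.
#' @return numeric n x 2 matrix of points within bounds.
#' @examples
#' range(sampleTestDensity(100, seed = 1))
#' @export
sampleTestDensity <- function(n, id = 1, bounds = c(-3, 3), seed = 1L) {
  pars <- mixtureParams(id)
  withSeed(seed, {
    out <- matrix(numeric(0), 0, 2)
    while (nrow(out) < n) {
      k <- sample.int(length(pars$w), n, replace = TRUE, prob = pars$w)
      x <- stats::rnorm(n, pars$mu[k, 1], pars$sd[k, 1])
      y <- stats::rnorm(n, pars$mu[k, 2], pars$sd[k, 2])
      ok <- x >= bounds[1] & x <= bounds[2] & y >= bounds[1] & y <= bounds[2]
      out <- rbind(out, cbind(x[ok], y[ok]))
    }
    out[seq_len(n), , drop = FALSE]
  })
}

## Midpoint-quadrature grid of a test density aligned with M bins per axis
## (sub subcells per bin per axis). Returns the (M*sub) x (M*sub) matrix of
## density values, normalized over the box.
densityGrid <- function(id, M, sub, bounds = c(-3, 3)) {
  pars <- mixtureParams(id)
  ng <- M * sub
  g <- bounds[1] + (seq_len(ng) - 0.5) * diff(bounds) / ng
  outer(g, g, mixtureDensity, pars = pars) / mixtureMass(pars, bounds)
}

#' L2 convergence-rate experiment for the histogram estimator
#'
#' Measures the mean L2 estimation error of the bivariate histogram as a
#' function of the sample size, with the bandwidth following the optimal
#' schedule \code{h proportional to n^(-1/4)} (implemented as
#' \code{M = round(n^(1/4))} bins per axis). For a twice continuously
#' differentiable density the error is expected to scale as
#' \code{n^(-1/4)}, i.e. a log-log slope of -1/4. The error integral is
#' computed by midpoint quadrature on a bin-aligned grid.
#'
#' @param ns sample sizes (default \code{2^(8:16)}).
#' @param reps replicates per sample size (default 20).
#' @param sub quadrature subcells per bin per axis (default 40).
#' @param seed integer seed.
#' @return list with \code{table} (data.frame of n and mean L2 error) and
#'   \code{slope} (fitted log-log slope).
#' @examples
#' \donttest{
#' histogramRateExperiment(ns = 2^(8:10), reps = 3, seed = 1)$slope
#' }
#' @export
histogramRateExperiment <- function(ns = 2^(8:16), reps = 20, sub = 40,
                                    seed = 1L) {
  bounds <- c(-3, 3)
  err <- vapply(seq_along(ns), function(ii) {
    n <- ns[ii]
    M <- max(2L, as.integer(round(n^0.25)))
    h <- diff(bounds) / M
    PG <- densityGrid(1, M, sub, bounds)
    bx <- rep(seq_len(M), each = sub)
    cell <- (diff(bounds) / (M * sub))^2
    mean(vapply(seq_len(reps), function(r) {
      S <- sampleTestDensity(n, id = 1, bounds = bounds,
                             seed = subSeed(seed, 1000 * ii + r))
      est <- densityValues(histogramDensity(S, bins = M, bounds = bounds))
      sqrt(sum((est[bx, bx] - PG)^2) * cell)
    }, numeric(1)))
  }, numeric(1))
  tab <- data.frame(n = ns, meanError = err)
  list(table = tab,
       slope = unname(stats::coef(stats::lm(log(err) ~ log(ns)))[2]))
}

#' Distance-consistency experiment
#'
#' Checks that the sample L2 distance between the histogram estimates of
#' two fixed smooth densities approaches the true (quadrature) L2 distance
#' between the densities as the sample size grows, with the consistent
#' bandwidth schedule \code{M = round(n^(1/4))}. Reports the median
#' absolute deviation from the true distance at each sample size.
#'
#' @param ns sample sizes (default \code{c(1e2, 1e3, 1e4)}).
#' @param reps replicates per sample size (default 15).
#' @param sub quadrature subcells per bin per axis (default 60).
#' @param seed integer seed.
#' @return list with \code{trueDistance}, and \code{table} (data.frame of
#'   n and median absolute error of the sample distance).
#' @examples
#' \donttest{
#' distanceConsistencyExperiment(ns = c(100, 1000), reps = 3, seed = 1)
#' }
#' @export
distanceConsistencyExperiment <- function(ns = c(1e2, 1e3, 1e4), reps = 15,
                                          sub = 60, seed = 1L) {
  bounds <- c(-3, 3)
  ## true L2 distance by fine midpoint quadrature
  ng <- 720
  g <- bounds[1] + (seq_len(ng) - 0.5) * diff(bounds) / ng
  p1 <- outer(g, g, mixtureDensity, pars = mixtureParams(1)) /
    mixtureMass(mixtureParams(1), bounds)
  p2 <- outer(g, g, mixtureDensity, pars = mixtureParams(2)) /
    mixtureMass(mixtureParams(2), bounds)
  dTrue <- sqrt(sum((p1 - p2)^2) * (diff(bounds) / ng)^2)
  med <- vapply(seq_along(ns), function(ii) {
    n <- ns[ii]
    M <- max(2L, as.integer(round(n^0.25)))
    stats::median(vapply(seq_len(reps), function(r) {
      s1 <- sampleTestDensity(n, 1, bounds, seed = subSeed(seed, 10000 * ii + 2 * r))
      s2 <- sampleTestDensity(n, 2, bounds, seed = subSeed(seed, 10000 * ii + 2 * r + 1))
      d <- histogramDistance(histogramDensity(s1, M, bounds),
                             histogramDensity(s2, M, bounds))
      abs(d - dTrue)
    }, numeric(1)))
  }, numeric(1))
  list(trueDistance = dTrue,
       table = data.frame(n = ns, medianAbsError = med))
}
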