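test_that("length-scale heuristic matches brute-force neighbour averages", {
  ## two rows at known distance, one neighbour
  X2 <- rbind(c(0, 0), c(3, 4))
  expect_equal(estimateLengthScale(X2, kNeighbors = 1), 5)
  ## small grid, k = 3, full subsample: exhaustive oracle
  set.seed(61)
  X <- matrix(rnorm(10 * 4), 10, 4)
  D <- as.matrix(dist(X))
  oracle <- mean(vapply(1:10, function(r) {
    mean(sort(D[r, -r])[1:3])
  }, numeric(1)))
  expect_equal(estimateLengthScale(X, kNeighbors = 3, subsampleSize = 100),
               oracle, tolerance = 1e-12)
  ## k is capped at m - 1 for small clouds
  expect_equal(estimateLengthScale(X, kNeighbors = 50, subsampleSize = 100),
               mean(vapply(1:10, function(r) mean(sort(D[r, -r])),
                           numeric(1))))
  expect_error(estimateLengthScale(matrix(1, 4, 3)), "identical")
})

test_that("similarity matrix is the squared-exponential of feature distances", {
  ## analytic point: distance sigma gives exp(-1/2)
  X <- rbind(0, 2)
  W <- similarityMatrix(X, sigma1 = 2)
  expect_equal(W[1, 2], exp(-1 / 2))
  expect_equal(diag(W), c(1, 1))
  ## brute-force double loop oracle on random features
  set.seed(71)
  X <- matrix(rnorm(5 * 7), 5, 7)
  s <- 1.7
  W <- similarityMatrix(X, s)
  for (a in 1:5) for (b in 1:5)
    expect_equal(W[a, b], exp(-sum((X[a, ] - X[b, ])^2) / (2 * s^2)),
                 tolerance = 1e-12)
  expect_error(similarityMatrix(matrix(c(1, Inf), 1, 2), 1), "non-finite")
  expect_error(similarityMatrix(X, -1), "positive")
})

test_that("similarity decreases with distance and increases with sigma", {
  set.seed(81)
  X <- matrix(rnorm(20 * 3), 20, 3)
  D <- as.matrix(dist(X))
  W1 <- similarityMatrix(X, 1)
  W2 <- similarityMatrix(X, 2)
  off <- upper.tri(D)
  o <- order(D[off])
  expect_true(all(diff(W1[off][o]) <= 1e-15))      # non-increasing in distance
  expect_true(all(W2[off] >= W1[off]))             # non-decreasing in sigma
})

test_that("graph Laplacians have the expected spectral structure", {
  set.seed(91)
  for (r in 1:5) {
    X <- matrix(rnorm(12 * 4), 12, 4)
    W <- similarityMatrix(X, sigma1 = runif(1, 0.5, 3))
    L <- graphLaplacian(W)
    expect_lt(max(abs(rowSums(L))), 1e-10)
    expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    Ln <- graphLaplacian(W, normalized = TRUE)
    ev <- eigen(Ln, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_lte(max(ev), 2 + 1e-8)
  }
  expect_error(graphLaplacian(matrix(c(1, 2, 3, 1), 2, 2)), "symmetric")
  ## near-disconnected limit: normalized Laplacian eigenvalues near zero
  Wd <- diag(2) + 1e-14
  evd <- eigen(graphLaplacian(Wd, normalized = TRUE),
               only.values = TRUE)$values
  expect_lt(max(abs(evd)), 1e-10)
})

test_that("kernel matrix defaults to the similarity matrix and is PSD", {
  set.seed(101)
  X <- matrix(rnorm(15 * 6), 15, 6)
  s <- estimateLengthScale(X, kNeighbors = 5)
  expect_identical(kernelValues(kernelMatrix(X, s)), similarityMatrix(X, s))
  expect_gte(min(eigen(kernelValues(kernelMatrix(X, s)), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  ## single row degenerates to the 1 x 1 identity
  expect_equal(kernelValues(kernelMatrix(matrix(1:3, 1), 2)),
               matrix(1, 1, 1))
})

test_that("manifoldGraph bundles W, degrees and both Laplacians coherently", {
  set.seed(111)
  X <- matrix(rnorm(18 * 4), 18, 4)
  g <- manifoldGraph(X, sigma1 = 1.4)
  expect_equal(similarity(g), similarityMatrix(X, 1.4))
  expect_equal(laplacian(g, normalized = FALSE),
               graphLaplacian(similarity(g)))
  expect_equal(laplacian(g), graphLaplacian(similarity(g), normalized = TRUE))
  expect_equal(lengthScale(g), 1.4)
})

test_that("the histogram scatter distance is a pseudo-metric on triples", {
  set.seed(121)
  for (r in 1:100) {
    n <- sample(5:60, 1)
    a <- histogramDensity(randomScatter(n), bins = 15)
    b <- histogramDensity(randomScatter(n), bins = 15)
    c_ <- histogramDensity(randomScatter(n), bins = 15)
    expect_identical(histogramDistance(a, a), 0)
    expect_identical(histogramDistance(a, b), histogramDistance(b, a))
    expect_lte(histogramDistance(a, c_),
               histogramDistance(a, b) + histogramDistance(b, c_) + 1e-9)
  }
})
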