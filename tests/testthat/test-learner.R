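test_that("pair enumeration counts and round-trips correctly", {
  idx3 <- buildPairIndex(3)
  expect_equal(npairs(idx3), 6)
  idx50 <- buildPairIndex(50, includeDiagonal = TRUE)
  expect_equal(npairs(idx50), 2500)
  for (idx in list(idx3, idx50, buildPairIndex(5))) {
    pm <- pairMatrix(idx)
    expect_identical(kOf(idx, pm[, 1], pm[, 2]), seq_len(npairs(idx)))
  }
  expect_error(buildPairIndex(1), "at least 2")
  expect_error(kOf(idx3, 1, 1), "not enumerated")
  expect_error(kOf(idx3, "x", "y"), "unknown")
})

test_that("label assembly maps edges, rejects conflicts, fills the diagonal", {
  idx <- buildPairIndex(3, varNames = c("a", "b", "c"))
  expect_error(assembleLabels(data.frame(source = character(0),
                                         target = character(0),
                                         label = numeric(0)), idx),
               "undefined without background knowledge")
  lab <- assembleLabels(data.frame(source = c("a", "b"),
                                   target = c("b", "c"),
                                   label = c(1, -1)), idx)
  expect_identical(labelledPairs(lab), kOf(idx, c("a", "b"), c("b", "c")))
  expect_equal(length(unlabelledPairs(lab)), 4)
  expect_identical(semantics(lab), "ancestral")
  ## duplicates: agreeing collapse, conflicting error
  expect_silent(assembleLabels(data.frame(source = c("a", "a"),
                                          target = c("b", "b"),
                                          label = c(1, 1)), idx))
  expect_error(assembleLabels(data.frame(source = c("a", "a"),
                                         target = c("b", "b"),
                                         label = c(1, -1)), idx),
               "conflicting")
  expect_error(assembleLabels(data.frame(source = "z", target = "b",
                                         label = 1), idx), "unknown")
  ## both orientations labelled +1 is flagged as a possible cycle
  expect_message(assembleLabels(data.frame(source = c("a", "b"),
                                           target = c("b", "a"),
                                           label = c(1, 1)), idx),
                 "both orientations")
  ## all pairs labelled leaves nothing to estimate
  pm <- pairMatrix(idx)
  labAll <- assembleLabels(data.frame(source = variableNames(idx)[pm[, 1]],
                                      target = variableNames(idx)[pm[, 2]],
                                      label = rep(1, 6)), idx)
  expect_length(unlabelledPairs(labAll), 0)
  ## diagonal-including index auto-labels self-pairs +1
  idxD <- buildPairIndex(3, includeDiagonal = TRUE,
                         varNames = c("a", "b", "c"))
  labD <- assembleLabels(data.frame(source = "a", target = "b", label = -1),
                         idxD)
  dk <- kOf(idxD, 1:3, 1:3)
  expect_true(all(dk %in% labelledPairs(labD)))
  expect_true(all(trainingLabels(labD)[match(dk, labelledPairs(labD))] == 1))
})

test_that("the end-to-end estimator is deterministic and self-consistent", {
  set.seed(211)
  x <- matrix(rnorm(800), 100, 8, dimnames = list(NULL, paste0("g", 1:8)))
  idx <- buildPairIndex(8, varNames = colnames(x))
  lab <- sampleLabelsRandom(diag(0, 8) + (matrix(runif(64), 8, 8) < 0.3),
                            rho = 0.4, seed = 3)
  cfg <- mrclConfig(pcaDim = 20, seed = 9)
  r1 <- runMRCL(x, lab, cfg)
  r2 <- runMRCL(x, lab, cfg)
  expect_identical(edgeScores(r1), edgeScores(r2))
  ## edge set and predicted labels agree exactly
  sc <- edgeScores(r1)
  g <- causalGraph(r1)
  expect_setequal(paste(edges(g)$source, edges(g)$target),
                  paste(sc$source, sc$target)[sc$predictedLabel > 0])
  ## unlabelled pairs: +1 iff score strictly positive
  u <- sc[!sc$labelled, ]
  expect_identical(u$predictedLabel, ifelse(u$score > 0, 1, -1))
  ## labelled pairs keep their known labels in the graph
  l <- sc[sc$labelled, ]
  expect_identical(l$predictedLabel, trainingLabels(lab))
  ## semantics tag survives the pipeline
  expect_identical(semantics(causalGraph(r1)), semantics(lab))
})

test_that("pipeline errors are tagged with the failing stage", {
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  x[, 2] <- 1                                  # constant column
  lab <- sampleLabelsRandom(diag(0, 4), rho = 0.5, seed = 1)
  expect_error(runMRCL(x, lab), "standardize_truncate")
})

test_that("labels built for another enumeration are refused", {
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  lab5 <- sampleLabelsRandom(diag(0, 5), rho = 0.5, seed = 1)
  expect_error(runMRCL(x, lab5), "different pair enumeration")
})
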