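makeScreen <- function(seed = 1, n = 6, e = 8, sigma = 0.01) {
  simulateScreen(simulationConfig(nNodes = n, nEdges = e, sigma = sigma,
                                  seed = seed))
}

test_that("a single-value grid is returned with its MSE table filled", {
  sim <- makeScreen()
  cv <- selectLambdaCV(sim$data, grid = 1, scheme = "loo_cells",
                       nHoldouts = 10, seed = 3)
  expect_equal(cv@bestLambda, 1)
  expect_equal(nrow(cv@mseTable), 1)
  expect_true(all(is.finite(cv@mseTable)))
  expect_true(all(cv@mseTable >= 0))
})

test_that("fold assignment and selection are pure functions of the seed", {
  sim <- makeScreen()
  cv1 <- selectLambdaCV(sim$data, grid = c(0, 1), k = 4, seed = 9)
  cv2 <- selectLambdaCV(sim$data, grid = c(0, 1), k = 4, seed = 9)
  expect_identical(cv1@foldAssignment, cv2@foldAssignment)
  expect_identical(cv1@bestLambda, cv2@bestLambda)
  expect_identical(cv1@mseTable, cv2@mseTable)
  cv3 <- selectLambdaCV(sim$data, grid = c(0, 1), k = 4, seed = 10)
  expect_false(identical(cv1@foldAssignment, cv3@foldAssignment))
})

test_that("the best penalty attains the minimal mean MSE", {
  sim <- makeScreen(seed = 4)
  cv <- selectLambdaCV(sim$data, grid = c(0, 0.1, 1, 10), k = 4, seed = 2)
  mm <- rowMeans(cv@mseTable, na.rm = TRUE)
  expect_true(all(cv@mseTable[is.finite(cv@mseTable)] >= 0))
  expect_lte(mm[paste0("lambda=", cv@bestLambda)], min(mm) + 1e-12)
})

test_that("held-out prediction on an identifiable chain hits the noise floor", {
  # a chain observed under a duplicated design (every single knockdown
  # and the control run twice) stays uniquely determined when any one
  # cell is left out — the twin experiment carries the same
  # constraint — so held-out MSE is O(sigma^2)
  sigma <- 0.01
  labels <- letters[1:4]
  net <- chainNetwork(labels)
  th <- setNames(rep(0.6, 4), labels)
  Z <- rbind(diag(4), 0, diag(4), 0)
  dimnames(Z) <- list(c(paste0("kd1_", labels), "ctrl1",
                        paste0("kd2_", labels), "ctrl2"), labels)
  cfg <- simulationConfig(nNodes = 4L, nEdges = 3L, sigma = sigma,
                          seed = 12L)
  pe <- simulateDataset(net, th, Z, cfg)
  cv <- selectLambdaCV(summarizeReplicates(pe), grid = c(0, 1),
                       scheme = "loo_cells", nHoldouts = 15, seed = 5)
  expect_lt(min(rowMeans(cv@mseTable)), 10 * sigma^2)
})

test_that("edge summaries follow the median/MAD keep rule", {
  w <- function(v) matrix(c(0, v, 0, 0), 2, 2)
  # identical runs: MAD 0, kept
  s1 <- summarizeEdges(list(w(0.5), w(0.5), w(0.5)))
  expect_equal(s1@medianWeight[2, 1], 0.5)
  expect_equal(s1@madWeight[2, 1], 0)
  expect_equal(s1@keepMask[2, 1], 1)
  # median 0, MAD 1: dropped
  s2 <- summarizeEdges(list(w(-1), w(0), w(1)))
  expect_equal(s2@medianWeight[2, 1], 0)
  expect_equal(s2@madWeight[2, 1], 1)
  expect_equal(s2@keepMask[2, 1], 0)
  expect_equal(s2@finalWeight[2, 1], 0)
  # single run: MAD 0, every non-zero edge kept
  s3 <- summarizeEdges(list(w(0.3)))
  expect_equal(s3@keepMask[2, 1], 1)
  expect_equal(s3@finalWeight[2, 1], 0.3)
})

test_that("edge summarization is invariant to run order", {
  set.seed(91)
  runs <- lapply(1:5, function(i) {
    W <- matrix(rnorm(16), 4, 4); diag(W) <- 0; W
  })
  a <- summarizeEdges(runs)
  b <- summarizeEdges(rev(runs))
  expect_equal(a@medianWeight, b@medianWeight)
  expect_equal(a@madWeight, b@madWeight)
})

test_that("noise-free chain data recover the exact chain", {
  sigma <- 0.005
  labels <- letters[1:4]
  net <- chainNetwork(labels)
  th <- setNames(rep(0.6, 4), labels)
  Z <- rbind(diag(4), 0)
  dimnames(Z) <- list(c(paste0("kd_", labels), "ctrl"), labels)
  pe <- simulateDataset(net, th, Z,
                        simulationConfig(nNodes = 4L, nEdges = 3L,
                                         sigma = sigma, seed = 8L))
  cv <- selectLambdaCV(summarizeReplicates(pe), grid = c(0, 1),
                       scheme = "loo_cells", nHoldouts = 12, seed = 2)
  es <- summarizeEdges(cv)
  W <- es@finalWeight
  for (i in 1:3) {
    expect_gt(abs(W[i, i + 1]), 0.1)   # every true edge present
    expect_equal(W[i + 1, i], 0)       # no reversed edge
  }
})

test_that("bootstrap aggregation is deterministic and degenerates cleanly", {
  sim <- makeScreen(seed = 6, n = 5, e = 6)
  b1 <- bootstrapAggregate(sim$data, nBoot = 2, seed = 4,
                           grid = c(0, 1), scheme = "loo_cells",
                           nHoldouts = 8)
  b2 <- bootstrapAggregate(sim$data, nBoot = 2, seed = 4,
                           grid = c(0, 1), scheme = "loo_cells",
                           nHoldouts = 8)
  expect_identical(b1@medianWeight, b2@medianWeight)
  # nBoot = 1 equals the summary of a single resampled CV run
  b3 <- bootstrapAggregate(sim$data, nBoot = 1, seed = 4,
                           grid = c(0, 1), scheme = "loo_cells",
                           nHoldouts = 8)
  expect_true(all(b3@madWeight == 0))
  # a single replicate triggers the degeneracy warning
  pe1 <- PerturbationExperiment(observationMatrix(summarizeReplicates(sim$data)),
                                sim$design, theta = sim$theta)
  expect_warning(bootstrapAggregate(pe1, nBoot = 1, grid = 1,
                                    scheme = "loo_cells", nHoldouts = 5,
                                    seed = 1),
                 "replicate")
})

test_that("bootstrap aggregation does not hurt ranking accuracy", {
  # paired comparison on small replicated screens: the bootstrap-
  # aggregated score should on average match or beat a single CV run
  reps <- 4
  deltas <- vapply(seq_len(reps), function(r) {
    sim <- makeScreen(seed = 30 + r, n = 5, e = 6, sigma = 0.15)
    truth <- (edgeWeights(sim$network) != 0) * 1
    single <- selectLambdaCV(sim$data, grid = c(0, 1),
                             scheme = "loo_cells", nHoldouts = 10,
                             seed = r)
    aucS <- rocPrAuc(abs(summarizeEdges(single)@medianWeight),
                     truth)$aucRoc
    agg <- bootstrapAggregate(sim$data, nBoot = 5, seed = r,
                              grid = c(0, 1), scheme = "loo_cells",
                              nHoldouts = 10)
    aucA <- rocPrAuc(abs(agg@medianWeight), truth)$aucRoc
    aucA - aucS
  }, 0)
  expect_gte(mean(deltas), -0.05)
})
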