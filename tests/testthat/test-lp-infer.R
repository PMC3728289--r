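test_that("variable and constraint bookkeeping matches the design", {
  # 3 genes, 4 experiments (three singles + unperturbed), all observed
  genes <- c("a", "b", "c")
  Z <- rbind(diag(3), 0)
  dimnames(Z) <- list(c("kd_a", "kd_b", "kd_c", "ctrl"), genes)
  X <- matrix(1, 4, 3, dimnames = dimnames(Z))
  X[cbind(1:3, 1:3)] <- 0            # targeted cells (excluded anyway)
  X[4, 3] <- 0; X[1, 2] <- 0; X[2, 3] <- 0
  X[1, 3] <- 0; X[3, 1] <- 1
  D <- ifelse(X == 1, 0.95, 0.245)
  spec <- buildLP(X, D, Z, theta = 0.6)
  expect_equal(sum(spec@varTag == "w+"), 6)
  expect_equal(sum(spec@varTag == "w-"), 6)
  expect_equal(sum(spec@varTag %in% c("b+", "b-")), 6)
  # inactive non-targeted observed cells
  nInact <- sum(Z == 0 & X == 0)
  expect_equal(spec@nInactive, nInact)
  expect_equal(sum(spec@varTag == "xi"), nInact)
  # one constraint per non-targeted observed cell
  expect_equal(nrow(spec@A), sum(Z == 0))
})

test_that("all-active data yields no slack variables and no lambda term", {
  Z <- rbind(diag(2), 0)
  X <- matrix(1, 3, 2); X[cbind(1:2, 1:2)] <- 0
  X[1, 2] <- 1; X[2, 1] <- 1          # non-targeted cells active
  X[cbind(1:2, 1:2)] <- NA            # targeted cells are never scored
  D <- matrix(0.95, 3, 2)
  spec <- buildLP(X, D, Z, theta = 0.6,
                  config = inferenceConfig(lambda = 7))
  expect_equal(spec@nInactive, 0L)
  expect_false(any(spec@varTag == "xi"))
  expect_true(all(spec@conTag == "active"))
})

test_that("missing parent values take their worst case", {
  # gene b active with parent a missing: a contributes 0 in the active
  # constraint; gene c inactive with parent a missing: a contributes 1
  genes <- c("a", "b", "c")
  Z <- matrix(0, 1, 3, dimnames = list("e1", genes))
  X <- matrix(c(NA, 1, 0), 1, 3, dimnames = dimnames(Z))
  D <- matrix(c(NA, 0.95, 0.245), 1, 3)
  spec <- buildLP(X, D, Z, theta = 0.6)
  A <- as.matrix(spec@A)
  nm <- names(spec@objective)
  activeRow <- which(spec@conTag == "active")
  inactiveRow <- which(spec@conTag == "inactive")
  expect_equal(A[activeRow, match("wp_a_b", nm)], 0)
  expect_equal(A[inactiveRow, match("wp_a_c", nm)], 1)
  expect_equal(A[inactiveRow, match("wm_a_c", nm)], -1)
})

test_that("empty constraint sets solve to the all-zero network", {
  Z <- matrix(1, 1, 2)  # every cell targeted
  X <- matrix(0, 1, 2)
  D <- matrix(0.1, 1, 2)
  expect_warning(spec <- buildLP(X, D, Z, theta = 0.6), "empty")
  res <- solveLP(spec)
  expect_equal(res@status, "optimal")
  expect_true(all(res@network@weights == 0))
  expect_equal(res@objectiveValue, 0)
})

test_that("noise-free chain: LP optimum is bounded by the generating net", {
  sc <- chainScreen(3)
  spec <- buildLP(sc$X, sc$D, sc$Z, sc$theta)
  res <- solveLP(spec)
  expect_equal(res@status, "optimal")
  # the generating network (chain weights 1, head bias 0.95) satisfies
  # every constraint: verify by direct substitution, then compare costs
  eps <- 0.1
  for (k in seq_len(nrow(sc$Z))) for (i in seq_len(3)) {
    if (sc$Z[k, i] == 1) next
    a <- sc$X[k, -i]; a[sc$Z[k, -i] == 1] <- 0
    lhs <- sum(edgeWeights(sc$net)[-i, i] * a) + biasTerms(sc$net)[i]
    if (sc$X[k, i] == 1) expect_gte(lhs, sc$theta[i] + eps)
    else expect_lte(lhs, sc$theta[i] - eps)
  }
  genCost <- sum(abs(edgeWeights(sc$net))) + sum(abs(biasTerms(sc$net)))
  expect_lte(res@objectiveValue, genCost + 1e-9)
})

test_that("LP optimum matches the brute-force grid on tiny instances", {
  set.seed(51)
  checked <- 0
  for (trial in 1:8) {
    n <- sample(2:3, 1)
    # states generated by a random signed network, so a slack-free
    # solution exists; one cell dropped to exercise missing handling
    W <- matrix(sample(c(0, 1, -1), n * n, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2)), n, n)
    diag(W) <- 0
    net <- SignalingNetwork(W, bias = sample(c(0, 0.95), n, replace = TRUE))
    theta <- rep(0.6, n)
    Z <- rbind(diag(n), 0)
    X <- propagateDesign(net, theta, Z)$states
    X[sample(length(X), 1)] <- NA
    D <- ifelse(is.na(X), NA, ifelse(X == 1, 0.95, 0.245))
    spec <- buildLP(X, D, Z, theta,
                    config = inferenceConfig(lambda = 1e6))
    res <- solveLP(spec)
    gridMin <- gridLPOracle(X, D, Z, theta)
    if (res@status == "optimal" && nrow(res@slacks) == 0) {
      expect_lte(res@objectiveValue, gridMin + 1e-9,
                 label = paste("trial", trial))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 2)
})

test_that("contradictory experiments force slack on the inactive side", {
  # two experiments with identical parent states; gene b observed
  # active in one and inactive in the other
  genes <- c("a", "b")
  Z <- matrix(0, 2, 2, dimnames = list(c("e1", "e2"), genes))
  X <- matrix(c(1, 1, 1, 0), 2, 2, dimnames = dimnames(Z))
  D <- ifelse(X == 1, 0.95, 0.245)
  cfg <- inferenceConfig(lambda = 1)
  spec <- buildLP(X, D, Z, theta = 0.6, config = cfg)
  res <- solveLP(spec, cfg)
  expect_equal(res@status, "optimal")
  expect_equal(nrow(res@slacks), 1)
  expect_equal(res@slacks$gene, "b")
  expect_equal(res@slacks$experiment, "e2")
  expect_gt(res@slacks$xi, 0)
})

test_that("slack stays zero when a slack-free solution exists", {
  sc <- chainScreen(4)
  cfg <- inferenceConfig(lambda = 0.5)
  res <- solveLP(buildLP(sc$X, sc$D, sc$Z, sc$theta, cfg), cfg)
  expect_equal(res@status, "optimal")
  expect_equal(nrow(res@slacks), 0)
})

test_that("L1 parsimony leaves off-chain weights at zero", {
  sc <- chainScreen(4)
  res <- solveLP(buildLP(sc$X, sc$D, sc$Z, sc$theta))
  W <- res@network@weights
  onChain <- cbind(1:3, 2:4)
  offMass <- sum(abs(W)) - sum(abs(W[onChain]))
  expect_lt(offMass, 1e-7)
  expect_true(all(abs(W[onChain]) > 0.1))
})

test_that("solutions scale linearly with theta and epsilon", {
  sc <- chainScreen(3)
  r1 <- solveLP(buildLP(sc$X, sc$D, sc$Z, sc$theta,
                        inferenceConfig(epsilon = 0.1)))
  k <- 2.5
  r2 <- solveLP(buildLP(sc$X, sc$D, sc$Z, sc$theta * k,
                        inferenceConfig(epsilon = 0.1 * k)))
  expect_equal(r2@network@weights, k * r1@network@weights,
               tolerance = 1e-6)
  expect_equal(r2@network@bias, k * r1@network@bias, tolerance = 1e-6)
})

test_that("edge priors force known interactions into the solution", {
  sc <- chainScreen(3)
  spec <- buildLP(sc$X, sc$D, sc$Z, sc$theta)
  cfg <- inferenceConfig(priorEdgeMin = 1)
  # an activation prior on an edge the data do not support
  spec2 <- addEdgePriors(spec, activations = cbind("c", "a"), config = cfg)
  res <- solveLP(spec2)
  expect_equal(res@status, "optimal")
  expect_gte(res@network@weights["c", "a"], 1 - 1e-7)
  # an inhibition prior pushes the weight below -priorEdgeMin
  spec3 <- addEdgePriors(spec, inhibitions = cbind("c", "a"), config = cfg)
  res3 <- solveLP(spec3)
  expect_lte(res3@network@weights["c", "a"], -1 + 1e-7)
  # empty prior set leaves the spec unchanged
  expect_equal(addEdgePriors(spec), spec)
  expect_error(addEdgePriors(spec, activations = cbind("a", "a")),
               "self-loop")
})

test_that("source/sink constraints are bookkept per node", {
  sc <- chainScreen(3)
  spec <- buildLP(sc$X, sc$D, sc$Z, sc$theta)
  n0 <- nrow(spec@A)
  spec2 <- addSourceSinkConstraints(spec, sources = "a", sinks = "c")
  # b gets in+out, a only out, c only in: 4 new rows
  expect_equal(nrow(spec2@A), n0 + 4)
  expect_equal(sum(spec2@conTag == "degree_in"), 2)
  expect_equal(sum(spec2@conTag == "degree_out"), 2)
  # every node both source and sink: unchanged
  spec3 <- addSourceSinkConstraints(spec, sources = c("a", "b", "c"),
                                    sinks = c("a", "b", "c"))
  expect_equal(nrow(spec3@A), n0)
  # the coupled program still solves and respects the degree bounds
  res <- solveLP(spec2)
  expect_equal(res@status, "optimal")
  W <- abs(res@network@weights)
  expect_gte(sum(W[, "b"]), 0.1 - 1e-7)
  expect_gte(sum(W["b", ]), 0.1 - 1e-7)
})

test_that("declared sources and sinks improve ten-node inference", {
  cfg <- simulationConfig(nNodes = 10, nEdges = 13, seed = 17)
  sim <- simulateScreen(cfg)
  truth <- (edgeWeights(sim$network) != 0) * 1
  plain <- inferNetwork(sim$data, config = inferenceConfig(lambda = 1))
  withSS <- inferNetwork(sim$data, config = inferenceConfig(lambda = 1),
                         sources = sourceNodes(sim$network),
                         sinks = sinkNodes(sim$network))
  aucPlain <- rocPrAuc(abs(edgeWeights(plain@network)), truth)$aucRoc
  aucSS <- rocPrAuc(abs(edgeWeights(withSS@network)), truth)$aucRoc
  expect_gte(aucSS, aucPlain - 0.05)
  expect_gt(aucSS, 0.5)
})

test_that("feasibility of every optimum is certified", {
  set.seed(61)
  for (trial in 1:5) {
    sim <- simulateScreen(simulationConfig(nNodes = 6, nEdges = 8,
                                           seed = 60 + trial))
    pe <- summarizeReplicates(sim$data)
    D <- observationMatrix(pe)
    X <- discretizeObservations(D, sim$theta)
    spec <- buildLP(X, D, designMatrix(pe), sim$theta)
    res <- solveLP(spec)
    expect_equal(res@status, "optimal")
    # re-assemble the solution vector and check all constraints
    x <- numeric(length(spec@objective))
    nm <- names(spec@objective)
    W <- res@network@weights; b <- res@network@bias
    for (v in seq_along(nm)) {
      p <- strsplit(nm[v], "_")[[1]]
      x[v] <- switch(p[1],
        wp = max(W[p[2], p[3]], 0), wm = max(-W[p[2], p[3]], 0),
        bp = max(b[p[2]], 0), bm = max(-b[p[2]], 0), 0)
    }
    xi <- which(spec@varTag == "xi")
    if (length(xi) && nrow(res@slacks)) {
      key <- paste0("xi_", res@slacks$gene, "_", res@slacks$experiment)
      x[match(key, nm)] <- res@slacks$xi
    }
    expect_true(isTRUE(checkFeasibility(spec, x, tol = 1e-6)))
  }
})

test_that("the LP serializes to CPLEX-LP text", {
  sc <- chainScreen(3)
  spec <- buildLP(sc$X, sc$D, sc$Z, sc$theta)
  f <- tempfile(fileext = ".lp")
  writeLPFormat(spec, f)
  txt <- readLines(f)
  expect_true(any(grepl("^Minimize", txt)))
  expect_true(any(grepl("^Subject To", txt)))
  expect_true(any(grepl("wp_a_b", txt)))
  expect_equal(txt[length(txt)], "End")
})
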