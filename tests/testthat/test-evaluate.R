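adj <- function(n, edges, labels = letters[seq_len(n)]) {
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (e in edges) W[e[1], e[2]] <- if (length(e) > 2) e[3] else 1
  W
}

test_that("metric identities hold and perfect predictions score 1", {
  r <- metricsFromCounts(10, 20, 0, 0)
  expect_equal(c(r@sp, r@sn, r@pr, r@ac), c(1, 1, 1, 1))
  set.seed(101)
  for (trial in 1:10) {
    cnt <- rmultinom(1, 60, rep(0.25, 4))
    r <- metricsFromCounts(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(r@sp, perturbLP:::roundHalfUp(cnt[2] / (cnt[2] + cnt[3]), 2))
    expect_equal(r@sn, perturbLP:::roundHalfUp(cnt[1] / (cnt[1] + cnt[4]), 2))
    expect_equal(r@ac, perturbLP:::roundHalfUp((cnt[1] + cnt[2]) / 60, 2))
  }
})

test_that("directed confusion counts cover all ordered pairs", {
  ref <- adj(3, list(c(1, 2), c(2, 3)))
  pred <- adj(3, list(c(1, 2), c(3, 1)))
  r <- confusionMetrics(pred, ref, mode = "directed")
  expect_equal(r@tp + r@tn + r@fp + r@fn, 6)
  expect_equal(r@tp, 1)  # a->b
  expect_equal(r@fp, 1)  # c->a
  expect_equal(r@fn, 1)  # b->c
  expect_equal(r@tn, 3)
  expect_error(
    confusionMetrics(adj(2, list(c(1, 2)), c("x", "y")), ref), "x")
})

test_that("relaxed scoring credits reversed and path-mediated edges", {
  # ref: a -> b -> c ; prediction: b -> a (reversed) and a -> c
  # (indirect via b)
  ref <- adj(3, list(c(1, 2), c(2, 3)))
  pred <- adj(3, list(c(2, 1), c(1, 3)))
  dir <- confusionMetrics(pred, ref, mode = "directed")
  expect_equal(dir@tp, 0)
  rel <- confusionMetrics(pred, ref, mode = "rep")
  expect_equal(rel@tp, 2)
  expect_equal(rel@fp, 0)
  # both reference edges are matched under the relaxed rule (b->a
  # reversed covers a->b; the predicted path b->a->c covers b->c)
  expect_equal(rel@fn, 0)
})

test_that("unsigned mode scores unordered pairs", {
  ref <- adj(3, list(c(1, 2)))
  pred <- adj(3, list(c(2, 1)))
  r <- confusionMetrics(pred, ref, mode = "unsigned")
  expect_equal(r@tp, 1)
  expect_equal(r@tp + r@tn + r@fp + r@fn, 3)
})

test_that("ROC/PR areas: separation gives 1, random scores give 1/2", {
  ref <- adj(4, list(c(1, 2), c(2, 3), c(3, 4)))
  scores <- ifelse(ref != 0, 2, 1)
  diag(scores) <- 0
  a <- rocPrAuc(scores, ref)
  expect_equal(a$aucRoc, 1)
  expect_equal(a$aucPr, 1)
  set.seed(111)
  nulls <- vapply(1:400, function(i) {
    s <- matrix(runif(16), 4, 4)
    rocPrAuc(s, ref)$aucRoc
  }, 0)
  expect_equal(mean(nulls), 0.5, tolerance = 0.03)
})

test_that("ROC area equals the exhaustive threshold oracle", {
  set.seed(121)
  for (trial in 1:20) {
    n <- 5
    ref <- matrix(rbinom(n * n, 1, 0.3), n, n); diag(ref) <- 0
    if (all(ref == 0) || all(ref[row(ref) != col(ref)] == 1)) next
    s <- matrix(sample(seq(0, 1, 0.1), n * n, replace = TRUE), n, n)
    off <- row(ref) != col(ref)
    expect_equal(rocPrAuc(s, ref)$aucRoc, aucOracle(s[off], ref[off] == 1))
  }
})

test_that("ROC area agrees with pROC and survives monotone rescoring", {
  library(pROC)
  set.seed(131)
  ref <- matrix(rbinom(36, 1, 0.3), 6, 6); diag(ref) <- 0
  s <- matrix(runif(36), 6, 6)
  off <- row(ref) != col(ref)
  ours <- rocPrAuc(s, ref)$aucRoc
  theirs <- as.numeric(auc(roc(ref[off], s[off], quiet = TRUE,
                               direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
  # strictly monotone transformations leave the area unchanged
  expect_equal(rocPrAuc(exp(3 * s), ref)$aucRoc, ours)
})

test_that("three-class evaluation scores signed recovery", {
  ref <- adj(4, list(c(1, 2, 1), c(2, 3, -1), c(3, 4, 1)))
  perfect <- threeClassAuc(ref, ref)
  expect_equal(perfect$auc, 1)
  # matches an independent macro-average computed per class
  set.seed(141)
  W <- matrix(rnorm(16), 4, 4); diag(W) <- 0
  got <- threeClassAuc(W, ref)
  off <- row(W) != col(W)
  w <- W[off]; r <- sign(ref[off])
  expected <- mean(c(aucOracle(w, r == 1), aucOracle(-abs(w), r == 0),
                     aucOracle(-w, r == -1)))
  expect_equal(got$auc, expected)
  # a reference without inhibitions skips that class
  refPos <- adj(4, list(c(1, 2, 1)))
  expect_true("inhibition" %in% threeClassAuc(W, refPos)$skipped)
})

test_that("three-class chance level is calibrated at one half", {
  # the macro-averaged one-vs-rest variant is calibrated: random
  # guessing (permuted signed networks of the true edge count) scores
  # 0.5 on average, unlike evaluation schemes whose chance level
  # drifts with class imbalance
  ref <- adj(5, list(c(1, 2, 1), c(2, 3, -1), c(3, 4, 1), c(4, 5, -1)))
  set.seed(151)
  off <- which(diag(5) == 0)
  nulls <- vapply(1:400, function(i) {
    W <- matrix(0, 5, 5)
    W[sample(off, 4)] <- sample(c(1, -1), 4, replace = TRUE)
    threeClassAuc(W, ref)$auc
  }, 0)
  expect_equal(mean(nulls), 0.5, tolerance = 0.02)
})

test_that("permutation p-values hit their boundary cases", {
  ref <- adj(4, list(c(1, 2), c(2, 3)))
  # perfect observed value beats every null draw
  top <- permutationBaseline(ref, metric = "auc_roc", observed = 1.000001,
                             nPerm = 99, seed = 2)
  expect_equal(top$p, 1 / 100)
  worst <- permutationBaseline(ref, metric = "auc_roc", observed = -1,
                               nPerm = 99, seed = 2)
  expect_equal(worst$p, 1)
  # reproducible null sample
  again <- permutationBaseline(ref, metric = "auc_roc", observed = 1.000001,
                               nPerm = 99, seed = 2)
  expect_identical(top$null, again$null)
})

test_that("the permutation null matches the hypergeometric expectation", {
  # E edges relocated among N slots overlap the truth E^2/N times on
  # average; sensitivity is overlap / E
  n <- 6; E <- 8; N <- n * (n - 1)
  set.seed(161)
  W <- matrix(0, n, n)
  W[sample(which(diag(n) == 0), E)] <- 1
  null <- permutationBaseline(W, metric = "sn", nPerm = 400, seed = 3)
  expect_equal(null$mean, E / N, tolerance = 0.02)
})

test_that("transitive closure matches Floyd-Warshall and is idempotent", {
  chain <- adj(3, list(c(1, 2), c(2, 3)))
  cl <- transitiveClosure(chain)
  expect_equal(cl["a", "c"], 1)
  expect_equal(transitiveClosure(cl), cl)
  set.seed(171)
  for (trial in 1:15) {
    A <- matrix(rbinom(36, 1, 0.25), 6, 6); diag(A) <- 0
    off <- row(A) != col(A)   # self-loops are excluded by the model
    expect_equal((transitiveClosure(A) == 1)[off], fwReach(A)[off],
                 ignore_attr = TRUE)
    # monotone: closing a supergraph never removes closure edges
    B <- A; B[sample(which(diag(6) == 0), 2)] <- 1
    expect_true(all(transitiveClosure(B) >= transitiveClosure(A)))
  }
})
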