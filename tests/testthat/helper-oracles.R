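# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: topological evaluation for acyclic
# propagation, exhaustive fixed-point enumeration, a brute-force grid
# minimizer for small LPs, explicit threshold-sweep AUC, and
# Floyd-Warshall reachability.

chainNetwork <- function(labels = c("s", "a", "t"), biasHead = 0.95) {
  n <- length(labels)
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) W[i, i + 1L] <- 1
  SignalingNetwork(W, bias = c(biasHead, rep(0, n - 1L)),
                   sources = labels[1L], sinks = labels[n])
}

# evaluation of the threshold model in topological order (DAGs only)
topoEvalOracle <- function(W, b, theta, kd) {
  n <- nrow(W)
  indeg <- colSums(W != 0)
  order <- integer(0)
  left <- rep(TRUE, n)
  while (any(left)) {
    ready <- which(left & indeg == 0)
    if (!length(ready)) stop("graph is not acyclic")
    order <- c(order, ready)
    left[ready] <- FALSE
    for (r in ready) indeg <- indeg - (W[r, ] != 0)
  }
  x <- numeric(n)
  for (i in order) {
    x[i] <- if (kd[i]) 0 else as.numeric(sum(W[, i] * x) + b[i] >= theta[i])
  }
  x
}

# all binary states satisfying the fixed-point equations
enumFixedPoints <- function(W, b, theta, kd) {
  n <- nrow(W)
  out <- list()
  for (code in 0:(2^n - 1L)) {
    x <- as.numeric(bitwAnd(bitwShiftR(code, 0:(n - 1L)), 1L))
    ok <- TRUE
    for (i in seq_len(n)) {
      want <- if (kd[i]) 0 else
        as.numeric(sum(W[, i] * x) + b[i] >= theta[i])
      if (x[i] != want) { ok <- FALSE; break }
    }
    if (ok) out[[length(out) + 1L]] <- x
  }
  out
}

# brute-force minimum of the slack-free LP objective over a discrete
# grid w in {-1,0,1}, b in {0,0.5,1}; returns Inf when no grid point is
# feasible. Constraint semantics re-implemented from scratch.
gridLPOracle <- function(X, D, Z, theta, eps = 0.1) {
  n <- ncol(Z); m <- nrow(Z)
  offDiag <- which(diag(n) == 0)
  nW <- length(offDiag)
  wLevels <- c(-1, 0, 1); bLevels <- c(0, 0.5, 1)
  best <- Inf
  wGrid <- as.matrix(expand.grid(rep(list(wLevels), nW)))
  bGrid <- as.matrix(expand.grid(rep(list(bLevels), n)))
  for (wi in seq_len(nrow(wGrid))) {
    W <- matrix(0, n, n)
    W[offDiag] <- wGrid[wi, ]
    costW <- sum(abs(W))
    if (costW >= best) next
    for (bi in seq_len(nrow(bGrid))) {
      b <- bGrid[bi, ]
      cost <- costW + sum(abs(b))
      if (cost >= best) next
      feasible <- TRUE
      for (k in seq_len(m)) {
        for (i in seq_len(n)) {
          if (Z[k, i] == 1 || is.na(X[k, i])) next
          a <- X[k, -i]
          a[Z[k, -i] == 1] <- 0
          a[is.na(a)] <- if (X[k, i] == 1) 0 else 1
          lhs <- sum(W[-i, i] * a) + b[i]
          ok <- if (X[k, i] == 1) lhs >= theta[i] + eps
                else lhs <= theta[i] - eps
          if (!ok) { feasible <- FALSE; break }
        }
        if (!feasible) break
      }
      if (feasible) best <- cost
    }
  }
  best
}

# explicit threshold-sweep ROC area (ties included simultaneously)
aucOracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- rbind(c(0, 0), t(vapply(thr, function(t) {
    sel <- scores >= t
    c(sum(!labels[sel]) / sum(!labels), sum(labels[sel]) / sum(labels))
  }, numeric(2))))
  sum(diff(pts[, 1L]) * (head(pts[, 2L], -1) + pts[-1L, 2L]) / 2)
}

# Floyd-Warshall reachability
fwReach <- function(adj) {
  n <- nrow(adj)
  R <- adj != 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (R[i, k] && R[k, j]) R[i, j] <- TRUE
  R
}

# small fully observed screen: chain with complete single-knockdown
# design plus control, exact (noise-free) measurements
chainScreen <- function(n = 3L, muA = 0.95, muI = 0.245, theta = 0.6) {
  labels <- letters[seq_len(n)]
  net <- chainNetwork(labels)
  th <- setNames(rep(theta, n), labels)
  Z <- rbind(diag(n), 0)
  dimnames(Z) <- list(c(paste0("kd_", labels), "control"), labels)
  st <- propagateDesign(net, th, Z)$states
  D <- ifelse(st == 1, muA, muI)
  list(net = net, theta = th, Z = Z, X = st, D = D)
}
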