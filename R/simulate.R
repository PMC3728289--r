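# Simulator for RNAi knockdown screens. Ground-truth topologies are
# random sparse digraphs (standing in for curated pathway extracts);
# signal is propagated deterministically by the threshold model and
# measurements are drawn from the two-component Gaussian model.

#' Generate a random ground-truth signaling network
#'
#' Samples \code{nEdges} distinct ordered node pairs uniformly (no
#' self-loops), assigns weight +1, then flips a random
#' \code{fracInhibitory} subset to -1. Nodes without incoming edges are
#' the sources (receptor-like, carrying baseline activity); nodes
#' without outgoing edges are the sinks. Biases are
#' \code{sourceBiasMean} for sources and 0 otherwise; per-gene
#' thresholds are \code{thetaDefault}. Biological pathway extracts are
#' sparse, roughly 1.3 edges per node; callers emulate that density by
#' choosing \code{nEdges} accordingly. Connectivity and acyclicity are
#' not enforced.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return list with \code{network}
#'   (\code{\linkS4class{SignalingNetwork}}) and \code{theta} (named
#'   numeric).
#' @examples
#' generateNetwork(simulationConfig(nNodes = 10, nEdges = 7, seed = 2))
#' @export
generateNetwork <- function(config = simulationConfig()) {
  n <- config@nNodes
  nE <- config@nEdges
  set.seed(config@seed)
  nodes <- sprintf("g%02d", seq_len(n))
  pairs <- which(diag(n) == 0)  # linear indices of off-diagonal slots
  sel <- sample(pairs, nE)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  W[sel] <- 1
  nInh <- round(config@fracInhibitory * nE)
  if (nInh > 0) W[sample(sel, nInh)] <- -1
  sources <- nodes[colSums(W != 0) == 0]
  sinks <- nodes[rowSums(W != 0) == 0]
  bias <- ifelse(nodes %in% sources, config@sourceBiasMean, 0)
  net <- SignalingNetwork(W, bias = bias, sources = sources, sinks = sinks)
  list(network = net,
       theta = setNames(rep(config@thetaDefault, n), nodes))
}

#' Generate a knockdown design
#'
#' Single knockdowns of every gene, \code{nDouble} random double
#' knockdowns (distinct pairs, sampled without replacement) and one
#' unperturbed control experiment: \code{m = nNodes + nDouble + 1} rows.
#'
#' @param nodes node labels (or an integer node count).
#' @param nDouble number of double-knockdown experiments.
#' @param seed RNG seed for the double-knockdown pairs.
#' @return binary experiment x gene matrix with informative rownames.
#' @examples
#' generateDesign(10, nDouble = 5, seed = 1)  # 16 experiments
#' @export
generateDesign <- function(nodes, nDouble = 5L, seed = 1L) {
  if (is.numeric(nodes) && length(nodes) == 1L)
    nodes <- sprintf("g%02d", seq_len(nodes))
  n <- length(nodes)
  nDouble <- as.integer(nDouble)
  maxPairs <- n * (n - 1L) / 2L
  if (nDouble > maxPairs)
    stop("nDouble exceeds the number of distinct gene pairs")
  Z <- diag(n)
  rn <- paste0("kd_", nodes)
  if (nDouble > 0L) {
    set.seed(seed)
    pick <- sample(maxPairs, nDouble)
    allPairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    dz <- matrix(0, nDouble, n)
    for (r in seq_len(nDouble)) dz[r, allPairs[pick[r], ]] <- 1
    Z <- rbind(Z, dz)
    rn <- c(rn, apply(allPairs[pick, , drop = FALSE], 1L, function(p)
      paste0("kd_", nodes[p[1L]], ".", nodes[p[2L]])))
  }
  Z <- rbind(Z, 0)
  rownames(Z) <- c(rn, "control")
  colnames(Z) <- nodes
  Z
}

#' Simulate noisy replicate observations for a knockdown design
#'
#' For every replicate and experiment, source biases are redrawn from
#' N(\code{sourceBiasMean}, \code{sourceBiasSd}) (unless the source is
#' itself targeted), activity states are propagated to their fixed
#' point, and each gene's measurement is drawn from
#' N(\code{muActive}, \code{sigma}) when active or
#' N(\code{muInactive}, \code{sigma}) when inactive.
#'
#' @param net a \code{\linkS4class{SignalingNetwork}} (unit weights for
#'   the canonical protocol).
#' @param theta per-gene thresholds.
#' @param Z binary experiment x gene design.
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return a \code{\linkS4class{PerturbationExperiment}} with assays
#'   \code{activity}, \code{knockdown} and \code{trueState};
#'   \code{metadata()$converged} flags per (replicate, experiment)
#'   propagation convergence.
#' @export
simulateDataset <- function(net, theta, Z, config = simulationConfig()) {
  Z <- as.matrix(Z)
  m <- nrow(Z); n <- ncol(Z)
  stopifnot(n == length(net@nodes))
  set.seed(config@seed + 1L)
  isSource <- net@nodes %in% net@sources
  obs <- states <- vector("list", config@nReplicates)
  conv <- matrix(TRUE, config@nReplicates, m)
  for (r in seq_len(config@nReplicates)) {
    Dr <- Xr <- matrix(0, m, n, dimnames = dimnames(Z))
    for (k in seq_len(m)) {
      bias <- net@bias
      redraw <- isSource & Z[k, ] == 0
      bias[redraw] <- rnorm(sum(redraw), config@sourceBiasMean,
                            config@sourceBiasSd)
      netk <- net
      netk@bias <- bias
      pr <- propagateStates(netk, theta, Z[k, ])
      conv[r, k] <- pr$converged
      Xr[k, ] <- pr$state
      mu <- ifelse(pr$state == 1, config@muActive, config@muInactive)
      Dr[k, ] <- rnorm(n, mu, config@sigma)
    }
    obs[[r]] <- Dr
    states[[r]] <- Xr
  }
  pe <- PerturbationExperiment(obs, Z, theta = theta, trueStates = states)
  S4Vectors::metadata(pe)$converged <- conv
  S4Vectors::metadata(pe)$seed <- config@seed
  pe
}

#' Simulate a complete knockdown screen
#'
#' Ground-truth network, design and noisy replicate data in one call; a
#' pure function of the configuration (and its seed).
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return list with \code{network}, \code{theta}, \code{design} and
#'   \code{data} (a \code{\linkS4class{PerturbationExperiment}}).
#' @examples
#' sim <- simulateScreen(simulationConfig(nNodes = 5, nEdges = 6, seed = 7))
#' sim$network
#' @export
simulateScreen <- function(config = simulationConfig()) {
  gt <- generateNetwork(config)
  Z <- generateDesign(gt$network@nodes, config@nDoubleKnockdowns,
                      seed = config@seed)
  pe <- simulateDataset(gt$network, gt$theta, Z, config)
  list(network = gt$network, theta = gt$theta, design = Z, data = pe)
}
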