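# End-to-end study protocols on simulated screens: the network-size
# benchmark and the ten-node noise / missing-data / prior-knowledge
# sweeps. Each protocol simulates, infers and scores; all randomness is
# a pure function of the seed argument.

#' Edge counts of the canonical ten-node study networks
#'
#' Ten sparse ten-node topologies with 5, 7, 7, 7, 7, 7, 8, 10, 12 and
#' 13 edges: five networks carry seven interactions, the remainder
#' span the 5-13 range.
#' @return integer vector of length 10.
#' @export
tenNodeEdgeCounts <- function() c(5L, 7L, 7L, 7L, 7L, 7L, 8L, 10L, 12L, 13L)

.cvAuc <- function(sim, lambdaGrid, k, seed, scheme = "kfold",
                   nHoldouts = 40L) {
  cv <- selectLambdaCV(sim$data, grid = lambdaGrid, k = k, seed = seed,
                       scheme = scheme, nHoldouts = nHoldouts)
  es <- summarizeEdges(cv)
  score <- abs(es@medianWeight)
  truth <- (edgeWeights(sim$network) != 0) * 1
  a <- rocPrAuc(score, truth)
  list(cv = cv, summary = es, aucRoc = a$aucRoc, aucPr = a$aucPr)
}

#' Network-size benchmark
#'
#' Simulates one sparse screen per network size (about 1.3 edges per
#' node, all activating, single knockdowns of every gene plus
#' \code{nDouble} random double knockdowns and one control, 3
#' replicates), selects the slack penalty by stratified k-fold
#' cross-validation, aggregates fold weights by the median and scores
#' |median weight| against the generating topology by ROC/PR area.
#'
#' @param sizes node counts.
#' @param edgesPerNode edge density of the generated topologies.
#' @param nDouble double knockdowns per screen.
#' @param sigma measurement noise s.d.
#' @param k cross-validation folds.
#' @param lambdaGrid penalty grid.
#' @param seed base seed; screen i uses \code{seed + i}.
#' @return list with \code{table} (one row per size: size, edges,
#'   bestLambda, aucRoc, aucPr) and \code{meanAucRoc},
#'   \code{meanAucPr}.
#' @export
benchmarkNetworkSizes <- function(sizes = c(16L, 24L, 32L, 44L, 52L),
                                  edgesPerNode = 1.3, nDouble = 5L,
                                  sigma = 0.01, k = 10L,
                                  lambdaGrid = c(0, 1, 10), seed = 1L) {
  rows <- lapply(seq_along(sizes), function(i) {
    n <- sizes[i]
    cfg <- simulationConfig(nNodes = n, nEdges = round(edgesPerNode * n),
                            nDoubleKnockdowns = nDouble, sigma = sigma,
                            seed = seed + i)
    sim <- simulateScreen(cfg)
    r <- .cvAuc(sim, lambdaGrid, k, seed = seed + i)
    data.frame(size = n, edges = cfg@nEdges,
               bestLambda = r$cv@bestLambda,
               aucRoc = r$aucRoc, aucPr = r$aucPr)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, meanAucRoc = mean(tab$aucRoc),
       meanAucPr = mean(tab$aucPr))
}

.tenNodeSim <- function(i, sigma, seed, fracInhibitory = 0) {
  cfg <- simulationConfig(nNodes = 10L, nEdges = tenNodeEdgeCounts()[i],
                          fracInhibitory = fracInhibitory, sigma = sigma,
                          seed = seed * 100L + i)
  simulateScreen(cfg)
}

#' Noise sweep on the ten-node study networks
#'
#' For each noise level, the ten canonical ten-node screens are
#' simulated, inferred with cross-validated penalty selection, and
#' scored by ROC area; a same-edge-count permutation baseline is
#' scored on the same references. Noise levels are paired by common
#' random numbers (identical topologies, designs and standardized
#' measurement draws across levels) so that differences between levels
#' reflect the noise alone rather than network sampling.
#'
#' @param sigmas noise levels.
#' @param lambdaGrid penalty grid.
#' @param nHoldouts held-out cells for the leave-one-cell-out CV used
#'   on these small screens.
#' @param nPerm permutations for the baseline.
#' @param seed base seed.
#' @return data.frame with one row per sigma: sigma, meanAucRoc,
#'   meanAucPr, nullAucRoc.
#' @export
noiseSweep <- function(sigmas = c(0.01, 0.05, 0.1, 0.2),
                       lambdaGrid = c(0, 0.1, 1, 10), nHoldouts = 40L,
                       nPerm = 50L, seed = 1L) {
  out <- lapply(seq_along(sigmas), function(si) {
    aucs <- vapply(seq_len(10L), function(i) {
      sim <- .tenNodeSim(i, sigmas[si], seed)
      r <- .cvAuc(sim, lambdaGrid, k = 2L, seed = seed + i,
                  scheme = "loo_cells", nHoldouts = nHoldouts)
      null <- permutationBaseline(edgeWeights(sim$network), "auc_roc",
                                  nPerm = nPerm, seed = seed + i)
      c(r$aucRoc, r$aucPr, null$mean)
    }, numeric(3))
    data.frame(sigma = sigmas[si], meanAucRoc = mean(aucs[1L, ]),
               meanAucPr = mean(aucs[2L, ]), nullAucRoc = mean(aucs[3L, ]))
  })
  do.call(rbind, out)
}

#' Missing-data sweep on the ten-node study networks
#'
#' Removes all measurements of a random fraction of genes before
#' inference (their incoming constraints vanish and their parent values
#' take worst-case substitutions) and compares the achieved ROC area
#' with the permutation baseline. Fractions are paired on the same
#' underlying screens.
#'
#' @param fracs fractions of genes fully unobserved.
#' @param sigma noise level of the underlying screens.
#' @param lambdaGrid penalty grid.
#' @param nHoldouts held-out cells for the leave-one-cell-out CV.
#' @param nPerm permutations for the baseline.
#' @param seed base seed.
#' @return data.frame with one row per fraction: frac, meanAucRoc,
#'   nullAucRoc.
#' @export
missingDataSweep <- function(fracs = c(0.1, 0.2, 0.4, 0.5), sigma = 0.01,
                             lambdaGrid = c(0, 0.1, 1, 10),
                             nHoldouts = 40L, nPerm = 50L, seed = 1L) {
  out <- lapply(seq_along(fracs), function(fi) {
    aucs <- vapply(seq_len(10L), function(i) {
      sim <- .tenNodeSim(i, sigma, seed)
      pe <- summarizeReplicates(sim$data)
      D <- observationMatrix(pe)
      set.seed(seed + fi * 2000L + i)
      hide <- sample(ncol(D), max(1L, round(fracs[fi] * ncol(D))))
      D[, hide] <- NA
      cv <- selectLambdaCV(D, Z = designMatrix(pe),
                           theta = activationThresholds(pe),
                           grid = lambdaGrid, scheme = "loo_cells",
                           nHoldouts = nHoldouts,
                           seed = seed + fi * 2000L + i)
      es <- summarizeEdges(cv)
      truth <- (edgeWeights(sim$network) != 0) * 1
      null <- permutationBaseline(truth, "auc_roc", nPerm = nPerm,
                                  seed = seed + fi * 2000L + i)
      c(rocPrAuc(abs(es@medianWeight), truth)$aucRoc, null$mean)
    }, numeric(2))
    data.frame(frac = fracs[fi], meanAucRoc = mean(aucs[1L, ]),
               nullAucRoc = mean(aucs[2L, ]))
  })
  do.call(rbind, out)
}

#' Prior-knowledge sweep on the ten-node study networks
#'
#' Supplies a growing random fraction of the true interactions as edge
#' priors (forcing their weight above \code{priorEdgeMin}) and records
#' the achieved ROC area.
#'
#' @param fracs fractions of true edges disclosed (0 = no priors).
#' @param sigma noise level.
#' @param lambda fixed slack penalty used for the sweep fits.
#' @param seed base seed.
#' @return data.frame with one row per fraction: frac, meanAucRoc.
#' @export
priorKnowledgeSweep <- function(fracs = c(0, 0.1, 0.25, 0.5, 1),
                                sigma = 0.01, lambda = 1, seed = 1L) {
  cfgInf <- inferenceConfig(lambda = lambda)
  out <- lapply(seq_along(fracs), function(fi) {
    aucs <- vapply(seq_len(10L), function(i) {
      sim <- .tenNodeSim(i, sigma, seed + 3000L)
      et <- edgeTable(sim$network)
      set.seed(seed + fi * 3000L + i)
      nPick <- round(fracs[fi] * nrow(et))
      act <- if (nPick > 0) et[sample(nrow(et), nPick), c("source", "target")]
      res <- inferNetwork(sim$data, config = cfgInf, activations = act)
      truth <- (edgeWeights(sim$network) != 0) * 1
      rocPrAuc(abs(edgeWeights(res@network)), truth)$aucRoc
    }, 0)
    data.frame(frac = fracs[fi], meanAucRoc = mean(aucs))
  })
  do.call(rbind, out)
}
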