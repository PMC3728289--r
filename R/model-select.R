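# Slack-penalty selection by cross-validated prediction error, and
# robust aggregation of edge weights across inference runs.

#' Default slack-penalty grid
#'
#' Ascending non-negative grid \code{c(0, 0.01, 0.1, 0.5, 1, 5, 10, 50)}.
#' @return numeric vector.
#' @export
defaultLambdaGrid <- function() c(0, 0.01, 0.1, 0.5, 1, 5, 10, 50)

.eligibleCells <- function(D, Z) {
  # held-out-eligible cells: observed and not directly targeted
  which(Z == 0 & !is.na(D), arr.ind = TRUE)
}

.assignFolds <- function(D, Z, theta, scheme, k, nHoldouts, seed) {
  cells <- .eligibleCells(D, Z)
  if (!nrow(cells)) stop("no held-out-eligible cells")
  X <- discretizeObservations(D, theta)
  state <- X[cells]
  set.seed(seed)
  if (scheme == "loo_cells") {
    nh <- min(nHoldouts, nrow(cells))
    pick <- sample(nrow(cells), nh)
    fold <- rep(NA_integer_, nrow(cells))
    fold[pick] <- seq_len(nh)
  } else {
    if (k < 2L || k > nrow(cells))
      stop("k must be between 2 and the number of eligible cells")
    fold <- rep(NA_integer_, nrow(cells))
    for (s in unique(state)) {       # stratified by discretized state
      idx <- which(state == s)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  rn <- rownames(Z) %||% paste0("exp", seq_len(nrow(Z)))
  cn <- colnames(Z) %||% paste0("g", seq_len(ncol(Z)))
  names(fold) <- paste0(rn[cells[, 1L]], ":", cn[cells[, 2L]])
  list(cells = cells, fold = fold)
}

.predictHeldOut <- function(fit, Dtrain, Xtrain, Z, theta, cells) {
  # propagate states from the fitted network per experiment involved,
  # then map states to expected observations via training-cell means
  model <- estimateObservationModel(Dtrain, Xtrain, theta)
  net <- fit@network
  pred <- numeric(nrow(cells))
  for (k in unique(cells[, 1L])) {
    st <- propagateStates(net, theta, Z[k, ])$state
    rows <- which(cells[, 1L] == k)
    mu <- ifelse(st == 1, model@muActive, model@muInactive)
    pred[rows] <- mu[cells[rows, 2L]]
  }
  pred
}

#' Select the slack penalty by cross-validation
#'
#' For every penalty on the grid and every fold, the fold's cells are
#' marked missing, the LP is fitted on the remaining data, activity
#' states are propagated from the fitted network for the affected
#' experiments, held-out observations are predicted through per-gene
#' Gaussian means estimated from training cells, and the squared
#' prediction error is accumulated. The penalty minimizing the mean MSE
#' wins; ties break to the smallest penalty. The held-out unit is a
#' single (experiment, gene) cell; \code{scheme = "loo_cells"} holds out
#' \code{nHoldouts} random cells one at a time, \code{"kfold"} uses a
#' state-stratified k-fold split. The fold assignment is a pure
#' function of \code{seed}.
#'
#' @param pe a \code{\linkS4class{PerturbationExperiment}} or an
#'   observation matrix (then \code{Z}, \code{theta} required).
#' @param Z,theta design and thresholds for matrix input.
#' @param grid ascending non-negative penalty grid.
#' @param scheme "kfold" or "loo_cells".
#' @param k number of folds for the k-fold scheme.
#' @param nHoldouts number of held-out cells for the LOO scheme.
#' @param config an \code{\linkS4class{InferenceConfig}} (its
#'   \code{lambda} is overridden by the grid).
#' @param seed fold-assignment seed.
#' @return a \code{\linkS4class{CVResult}}.
#' @export
selectLambdaCV <- function(pe, Z = NULL, theta = NULL,
                           grid = defaultLambdaGrid(),
                           scheme = c("kfold", "loo_cells"), k = 10L,
                           nHoldouts = 100L,
                           config = inferenceConfig(), seed = 1L) {
  scheme <- match.arg(scheme)
  if (is(pe, "PerturbationExperiment")) {
    if (anyDuplicated(colData(pe)$experiment))
      pe <- summarizeReplicates(pe)
    D <- observationMatrix(pe)
    Z <- designMatrix(pe)
    theta <- activationThresholds(pe)
  } else {
    D <- as.matrix(pe)
    if (is.null(Z) || is.null(theta))
      stop("Z and theta are required when pe is a plain matrix")
  }
  if (!length(grid) || is.unsorted(grid, strictly = TRUE) || any(grid < 0))
    stop("grid must be a non-empty ascending vector of non-negative values")
  theta <- .checkTheta(theta, colnames(Z))
  fa <- .assignFolds(D, Z, theta, scheme, as.integer(k),
                     as.integer(nHoldouts), as.integer(seed))
  folds <- sort(unique(fa$fold[!is.na(fa$fold)]))
  mse <- matrix(NA_real_, length(grid), length(folds),
                dimnames = list(paste0("lambda=", grid),
                                paste0("fold", folds)))
  weights <- vector("list", length(grid))
  for (gi in seq_along(grid)) weights[[gi]] <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    hold <- fa$cells[which(fa$fold == folds[fi]), , drop = FALSE]
    if (!nrow(hold)) {
      warning("fold ", folds[fi], " holds out no observed cells; skipped")
      next
    }
    Dtrain <- D
    Dtrain[hold] <- NA
    Xtrain <- discretizeObservations(Dtrain, theta)
    # the spec is identical across the grid except for the slack
    # penalty coefficient: build once per fold, swap the coefficient
    baseSpec <- buildLP(Xtrain, Dtrain, Z, theta, config)
    xiCols <- which(baseSpec@varTag == "xi")
    for (gi in seq_along(grid)) {
      cfg <- config
      cfg@lambda <- grid[gi]
      spec <- baseSpec
      if (length(xiCols))
        spec@objective[xiCols] <- if (cfg@normalizeSlack)
          cfg@lambda / length(xiCols) else cfg@lambda
      fit <- solveLP(spec, cfg)
      if (fit@status != "optimal") next
      pred <- .predictHeldOut(fit, Dtrain, Xtrain, Z, theta, hold)
      mse[gi, fi] <- mean((pred - D[hold])^2)
      weights[[gi]][[fi]] <- fit@network@weights
    }
  }
  meanMse <- rowMeans(mse, na.rm = TRUE)
  meanMse[!is.finite(meanMse)] <- Inf   # all folds failed at this lambda
  if (all(is.infinite(meanMse)))
    stop("no penalty on the grid produced an optimal fit in any fold")
  best <- which(meanMse <= min(meanMse) + 1e-12)[1L]  # tie: smallest lambda
  runWeights <- Filter(Negate(is.null), weights[[best]])
  new("CVResult", bestLambda = grid[best], mseTable = mse,
      lambdaGrid = as.numeric(grid), runWeights = runWeights,
      foldAssignment = fa$fold, seed = as.integer(seed))
}

#' Robust edge aggregation across runs
#'
#' Per ordered node pair, the median and the unscaled median absolute
#' deviation (\code{median(|w - median(w)|)}) of the weights across
#' runs are computed; an edge is kept only when its |median| exceeds
#' its MAD, i.e. when it was learned robustly across cross-validation
#' runs. The final weight is \code{median * keep}.
#'
#' @param runWeights list of weight matrices (or a
#'   \code{\linkS4class{CVResult}}).
#' @return an \code{\linkS4class{EdgeSummary}}.
#' @examples
#' w1 <- matrix(c(0, 0.5, 0, 0), 2); w2 <- matrix(c(0, 0.6, 0, 0), 2)
#' summarizeEdges(list(w1, w2))
#' @export
summarizeEdges <- function(runWeights) {
  if (is(runWeights, "CVResult")) runWeights <- runWeights@runWeights
  if (!length(runWeights)) stop("at least one run is required")
  dn <- dimnames(runWeights[[1L]])
  arr <- simplify2array(runWeights)
  med <- apply(arr, c(1L, 2L), median)
  madw <- apply(arr, c(1L, 2L), function(v) median(abs(v - median(v))))
  keep <- (abs(med) > madw) * 1
  diag(keep) <- 0
  dimnames(med) <- dimnames(madw) <- dimnames(keep) <- dn
  new("EdgeSummary", medianWeight = med, madWeight = madw,
      keepMask = keep, finalWeight = med * keep)
}

#' Bootstrap aggregation over replicates
#'
#' For replicate-rich data: each bootstrap sample redraws, per
#' (experiment, gene) cell, the cell's replicate values with
#' replacement, summarizes them, and runs the full cross-validated
#' inference; edge weights are then aggregated across bootstrap samples
#' with the median/MAD rule of \code{\link{summarizeEdges}}.
#'
#' @param pe a replicated \code{\linkS4class{PerturbationExperiment}}.
#' @param nBoot number of bootstrap samples.
#' @param summarizeMethod replicate summary, "mean" or "median".
#' @param seed RNG seed (resamples are a pure function of it).
#' @param ... passed on to \code{\link{selectLambdaCV}}.
#' @return an \code{\linkS4class{EdgeSummary}} across bootstrap samples.
#' @export
bootstrapAggregate <- function(pe, nBoot = 10L,
                               summarizeMethod = c("mean", "median"),
                               seed = 1L, ...) {
  summarizeMethod <- match.arg(summarizeMethod)
  stopifnot(is(pe, "PerturbationExperiment"), nBoot >= 1L)
  cd <- colData(pe)
  nrep <- max(cd$replicate)
  if (nrep < 2L)
    warning("fewer than 2 replicates: bootstrap degenerates to repetition")
  act <- assay(pe, "activity")
  exps <- unique(cd$experiment)
  genes <- rownames(pe)
  theta <- activationThresholds(pe)
  Z <- designMatrix(pe)
  set.seed(as.integer(seed))
  bootSeeds <- sample.int(2147483, nBoot)
  perSample <- vector("list", nBoot)
  for (b in seq_len(nBoot)) {
    set.seed(bootSeeds[b])
    Db <- matrix(NA_real_, length(exps), length(genes),
                 dimnames = list(exps, genes))
    for (e in seq_along(exps)) {
      cols <- which(cd$experiment == exps[e])
      for (g in seq_along(genes)) {
        v <- act[g, cols]
        v <- v[!is.na(v)]
        if (!length(v)) next
        vb <- v[sample.int(length(v), length(v), replace = TRUE)]
        Db[e, g] <- if (summarizeMethod == "mean") mean(vb) else median(vb)
      }
    }
    cv <- selectLambdaCV(Db, Z = Z, theta = theta, seed = bootSeeds[b], ...)
    perSample[[b]] <- summarizeEdges(cv)@medianWeight
  }
  summarizeEdges(perSample)
}
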