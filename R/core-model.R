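# Threshold activation model: a gene is active iff the weighted sum of
# its parents' states plus its bias reaches its threshold. Knocked-down
# genes are clamped inactive and removed from regulation.

roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.checkTheta <- function(theta, genes = NULL) {
  theta <- as.numeric(theta)
  if (any(is.na(theta)) || any(theta <= 0))
    stop("activation thresholds theta must be positive")
  if (!is.null(genes)) {
    theta <- rep_len(theta, length(genes))
    names(theta) <- genes
  }
  theta
}

#' Discretize observations against activation thresholds
#'
#' A measured value counts as active when it reaches the gene's
#' threshold (\code{d >= theta}; the boundary convention is applied
#' uniformly across the package). Missing observations stay missing.
#'
#' @param D experiment x gene numeric matrix (NA = missing).
#' @param theta positive per-gene thresholds (recycled if scalar).
#' @return binary matrix of the same shape, NA preserved.
#' @examples
#' discretizeObservations(matrix(c(0.95, 0.5, 0.2), 1), theta = 0.5)
#' @export
discretizeObservations <- function(D, theta) {
  D <- as.matrix(D)
  theta <- .checkTheta(theta, colnames(D))
  theta <- rep_len(theta, ncol(D))
  X <- (D >= matrix(theta, nrow(D), ncol(D), byrow = TRUE)) * 1
  dimnames(X) <- dimnames(D)
  X
}

#' Propagate activity states through a network under a knockdown
#'
#' Computes the fixed point of the threshold activation model: gene i is
#' active iff \code{sum_j w[j,i] x[j] + b[i] >= theta[i]}, with multiple
#' incoming activations aggregated additively (any sufficient parent set
#' activates; an OR-like semantics for unit weights). Knocked-down genes
#' are forced inactive and no longer subject to regulation. Propagation
#' is a synchronous fixed-point iteration started from the baseline
#' state \code{x0[i] = (b[i] >= theta[i]) & !knockdown}, exact on
#' acyclic graphs; oscillations (period-2 cycles) or a blown iteration
#' budget of \code{2 n} sweeps return the elementwise AND of the last
#' two states with \code{converged = FALSE}.
#'
#' @param net a \code{\linkS4class{SignalingNetwork}}.
#' @param theta positive per-gene thresholds.
#' @param knockdown binary vector over nodes (1 = silenced), or a
#'   character vector of node labels.
#' @return list with \code{state} (named 0/1 vector) and
#'   \code{converged} (logical).
#' @examples
#' w <- matrix(0, 3, 3, dimnames = rep(list(c("s","a","t")), 2))
#' w["s","a"] <- 1; w["a","t"] <- 1
#' net <- SignalingNetwork(w, bias = c(0.95, 0, 0))
#' propagateStates(net, 0.5, knockdown = "s")$state
#' @export
propagateStates <- function(net, theta, knockdown = NULL) {
  nodes <- net@nodes
  n <- length(nodes)
  theta <- .checkTheta(theta, nodes)
  kd <- logical(n)
  names(kd) <- nodes
  if (is.character(knockdown)) {
    bad <- setdiff(knockdown, nodes)
    if (length(bad)) stop("unknown knockdown targets: ",
                          paste(bad, collapse = ", "))
    kd[knockdown] <- TRUE
  } else if (!is.null(knockdown)) {
    kd <- rep_len(as.logical(knockdown), n)
  }
  W <- net@weights
  b <- net@bias
  x <- as.numeric(b >= theta & !kd)
  prev <- NULL
  for (it in seq_len(max(2L * n, 2L))) {
    inp <- drop(crossprod(W, x)) + b
    xn <- as.numeric(inp >= theta & !kd)
    if (identical(xn, x)) {
      names(x) <- nodes
      return(list(state = x, converged = TRUE))
    }
    if (!is.null(prev) && identical(xn, prev)) {  # period-2 oscillation
      x <- pmin(xn, x)
      names(x) <- nodes
      return(list(state = x, converged = FALSE))
    }
    prev <- x
    x <- xn
  }
  x <- pmin(x, prev)
  names(x) <- nodes
  list(state = x, converged = FALSE)
}

#' Propagate states for every experiment of a knockdown design
#'
#' @param net a \code{\linkS4class{SignalingNetwork}}.
#' @param theta per-gene thresholds.
#' @param Z binary experiment x gene design matrix.
#' @return list with \code{states} (experiment x gene binary matrix) and
#'   \code{converged} (logical per experiment).
#' @export
propagateDesign <- function(net, theta, Z) {
  Z <- as.matrix(Z)
  res <- apply(Z, 1L, function(z) propagateStates(net, theta, z),
               simplify = FALSE)
  states <- do.call(rbind, lapply(res, `[[`, "state"))
  rownames(states) <- rownames(Z)
  list(states = states,
       converged = vapply(res, `[[`, TRUE, "converged"))
}

#' Map predicted activity states to expected observations
#'
#' Replaces each binary state by the corresponding per-gene mean of the
#' two-component Gaussian measurement model (used for held-out
#' prediction in cross-validation).
#'
#' @param states binary vector or experiment x gene matrix.
#' @param model a \code{\linkS4class{GaussianObservationModel}} whose
#'   means are named by gene.
#' @return numeric object of the same shape.
#' @export
predictObservations <- function(states, model) {
  stopifnot(is(model, "GaussianObservationModel"))
  genes <- if (is.matrix(states)) colnames(states) else names(states)
  muA <- model@muActive
  muI <- model@muInactive
  if (!is.null(genes) && !is.null(names(muA))) {
    missing <- setdiff(genes, names(muA))
    if (length(missing))
      stop("no estimated observation means for gene(s): ",
           paste(missing, collapse = ", "))
    muA <- muA[genes]
    muI <- muI[genes]
  }
  if (is.matrix(states)) {
    mA <- matrix(muA, nrow(states), ncol(states), byrow = TRUE)
    mI <- matrix(muI, nrow(states), ncol(states), byrow = TRUE)
    out <- ifelse(states == 1, mA, mI)
    dimnames(out) <- dimnames(states)
  } else {
    out <- ifelse(states == 1, muA, muI)
    names(out) <- genes
  }
  out
}

#' Estimate a Gaussian observation model from data
#'
#' Per-gene means are estimated from observed cells split by their
#' discretized state. A gene observed in only one state falls back to
#' the global (all-gene) mean of the other state; with no global
#' information either, the threshold midpoint convention
#' \code{theta +/- epsilon} is used.
#'
#' @param D experiment x gene observation matrix.
#' @param X matching binary state matrix (typically
#'   \code{discretizeObservations(D, theta)}).
#' @param theta per-gene thresholds (fallback anchor).
#' @return a \code{\linkS4class{GaussianObservationModel}}.
#' @export
estimateObservationModel <- function(D, X, theta) {
  D <- as.matrix(D)
  theta <- .checkTheta(theta, colnames(D))
  theta <- rep_len(theta, ncol(D))
  gA <- mean(D[X == 1], na.rm = TRUE)
  gI <- mean(D[X == 0], na.rm = TRUE)
  muA <- vapply(seq_len(ncol(D)), function(i) {
    v <- D[X[, i] == 1 & !is.na(X[, i]), i]
    if (length(v <- v[!is.na(v)])) mean(v)
    else if (is.finite(gA)) gA else theta[i] + 0.1
  }, 0)
  muI <- vapply(seq_len(ncol(D)), function(i) {
    v <- D[X[, i] == 0 & !is.na(X[, i]), i]
    if (length(v <- v[!is.na(v)])) mean(v)
    else if (is.finite(gI)) gI else theta[i] - 0.1
  }, 0)
  # degenerate split (means on the wrong side of each other): nudge apart
  bad <- muA <= muI
  if (any(bad)) {
    mid <- (muA[bad] + muI[bad]) / 2
    muA[bad] <- mid + 1e-6
    muI[bad] <- mid - 1e-6
  }
  resid <- c(D[X == 1] - rep(muA, each = nrow(D))[X == 1],
             D[X == 0] - rep(muI, each = nrow(D))[X == 0])
  s <- stats::sd(resid[!is.na(resid)])
  if (!is.finite(s) || s <= 0) s <- 1e-6
  genes <- colnames(D)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(D)))
  new("GaussianObservationModel",
      muActive = setNames(muA, genes),
      muInactive = setNames(muI, genes), sigma = s)
}
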