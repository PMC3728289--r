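# Solving the assembled LP. The program separates over target genes
# unless out-degree constraints couple blocks: every active/inactive,
# prior-edge and in-degree row touches only the incoming-weight block of
# one gene. solveLP() exploits this and solves independent per-gene
# subprograms where possible, which keeps large-network inference fast.

.statusString <- function(code) {
  switch(as.character(code), "0" = "optimal", "1" = "unbounded",
         "2" = "iteration_limit", "3" = "infeasible", "unknown")
}

# densify the constraint system once, folding finite upper bounds into
# extra <= rows
.prepDense <- function(A, dir, rhs, upper) {
  Ad <- as.matrix(A)
  fin <- which(is.finite(upper))
  if (length(fin)) {
    Aub <- matrix(0, length(fin), ncol(Ad))
    Aub[cbind(seq_along(fin), fin)] <- 1
    Ad <- rbind(Ad, Aub)
    dir <- c(dir, rep("<=", length(fin)))
    rhs <- c(rhs, upper[fin])
  }
  list(A = Ad, dir = dir, rhs = rhs)
}

.solveDense <- function(obj, sys, maxIter = 100000L) {
  dcode <- c("<=" = -1L, "=" = 0L, ">=" = 1L)[sys$dir]
  res <- .simplex_solve(obj, sys$A, as.integer(dcode), sys$rhs,
                        as.integer(maxIter))
  res$status <- .statusString(res$status)
  if (!is.null(res$x)) res$x <- as.numeric(res$x)
  res
}

# solve min obj'x, A x dir rhs, 0 <= x <= upper (finite uppers become rows)
.solveBlock <- function(obj, A, dir, rhs, upper, maxIter = 100000L) {
  .solveDense(obj, .prepDense(A, dir, rhs, upper), maxIter)
}

# lexicographic solve: minimize obj, then among (near-)optimal points
# minimize the contradiction count `refine` (see the LPSpec class),
# pinning down a unique reconstruction when the L1 optimum is
# degenerate
.solveRefined <- function(obj, A, dir, rhs, upper, refine = NULL) {
  sys <- .prepDense(A, dir, rhs, upper)
  res <- .solveDense(obj, sys)
  if (res$status != "optimal" || is.null(refine) || all(refine == 0))
    return(res)
  # already contradiction-free: the secondary objective is at its bound
  if (sum(refine * res$x) <= 1e-12) return(res)
  sys2 <- list(A = rbind(sys$A, obj), dir = c(sys$dir, "<="),
               rhs = c(sys$rhs, res$value + 1e-8 * max(1, abs(res$value))))
  # a modest budget: the refinement is a tie-break, so on exhaustion
  # the primary optimum is returned unchanged
  res2 <- .solveDense(refine, sys2, maxIter = 3000L)
  if (res2$status != "optimal") return(res)
  res2$value <- sum(obj * res2$x)
  res2
}

#' Check primal feasibility of a solution
#'
#' @param spec an \code{\linkS4class{LPSpec}}.
#' @param x numeric solution vector in the spec's variable order.
#' @param tol feasibility tolerance.
#' @return TRUE when every constraint and bound holds within \code{tol};
#'   otherwise FALSE with attribute \code{"violation"} giving the worst
#'   violation.
#' @export
checkFeasibility <- function(spec, x, tol = 1e-7) {
  lhs <- as.numeric(spec@A %*% x)
  viol <- c(
    ifelse(spec@dir == "<=", lhs - spec@rhs,
           ifelse(spec@dir == ">=", spec@rhs - lhs, abs(lhs - spec@rhs))),
    -x,
    (x - spec@upper)[is.finite(spec@upper)])
  worst <- if (length(viol)) max(viol) else 0
  ok <- worst <= tol
  attr(ok, "violation") <- max(worst, 0)
  ok
}

#' Solve the network-inference linear program
#'
#' Decomposes the program into independent per-gene blocks when no
#' constraint couples genes (out-degree rows are the only coupling
#' rows), solves each with a two-phase simplex, asserts primal
#' feasibility of the optimum, and recombines the split variables into
#' signed weights and biases.
#'
#' @param spec an \code{\linkS4class{LPSpec}}.
#' @param config an \code{\linkS4class{InferenceConfig}} (supplies
#'   \code{solverTolerance}).
#' @return an \code{\linkS4class{InferenceResult}}; a non-optimal
#'   status is reported, never silently coerced.
#' @examples
#' sim <- simulateScreen(simulationConfig(nNodes = 4, nEdges = 4, seed = 1))
#' pe <- summarizeReplicates(sim$data)
#' D <- observationMatrix(pe)
#' X <- discretizeObservations(D, activationThresholds(pe))
#' spec <- buildLP(X, D, designMatrix(pe), activationThresholds(pe))
#' solveLP(spec)
#' @export
solveLP <- function(spec, config = inferenceConfig()) {
  n <- length(spec@nodes)
  nv <- length(spec@objective)
  x <- numeric(nv)
  coupling <- is.na(spec@conGene)
  status <- "optimal"
  refine <- if (length(spec@refine)) spec@refine else NULL
  if (any(coupling) && nrow(spec@A)) {
    res <- .solveRefined(spec@objective, spec@A, spec@dir, spec@rhs,
                         spec@upper, refine)
    status <- res$status
    if (status == "optimal") x <- res$x
  } else if (nrow(spec@A)) {
    for (i in seq_len(n)) {
      rows <- which(spec@conGene == i)
      cols <- which(spec@varGene == i)
      if (!length(rows)) next
      res <- .solveRefined(spec@objective[cols],
                           spec@A[rows, cols, drop = FALSE],
                           spec@dir[rows], spec@rhs[rows],
                           spec@upper[cols],
                           if (is.null(refine)) NULL else refine[cols])
      if (res$status != "optimal") {
        status <- res$status
        break
      }
      x[cols] <- res$x
    }
  }
  if (status == "optimal" && nrow(spec@A) &&
      !isTRUE(ok <- checkFeasibility(spec, x, config@solverTolerance)))
    stop("solver returned an optimum violating feasibility by ",
         format(attr(ok, "violation")), "; this indicates a numerical ",
         "failure, not a data problem")

  genes <- spec@nodes
  W <- matrix(0, n, n, dimnames = list(genes, genes))
  b <- setNames(numeric(n), genes)
  slacks <- data.frame(gene = character(), experiment = character(),
                       xi = numeric(), stringsAsFactors = FALSE)
  if (status == "optimal") {
    nm <- names(spec@objective)
    for (i in seq_len(n)) {
      cols <- which(spec@varGene == i & spec@varTag == "w+")
      colsM <- which(spec@varGene == i & spec@varTag == "w-")
      W[genes[-i], i] <- x[cols] - x[colsM]
      b[i] <- x[spec@varGene == i & spec@varTag == "b+"] -
        x[spec@varGene == i & spec@varTag == "b-"]
    }
    xiCols <- which(spec@varTag == "xi")
    nz <- xiCols[x[xiCols] > config@solverTolerance]
    if (length(nz)) {
      parts <- strsplit(sub("^xi_", "", nm[nz]), "_")
      slacks <- data.frame(
        gene = vapply(parts, `[`, "", 1L),
        experiment = vapply(parts, function(p)
          paste(p[-1L], collapse = "_"), ""),
        xi = x[nz], stringsAsFactors = FALSE)
    }
  }
  net <- SignalingNetwork(W, bias = b, nodes = genes)
  new("InferenceResult", network = net, slacks = slacks,
      objectiveValue = if (status == "optimal")
        sum(spec@objective * x) else NA_real_,
      status = status)
}

#' One-call network inference
#'
#' Convenience wrapper: discretize, assemble the LP (optionally with
#' edge priors and source/sink constraints) and solve at a fixed slack
#' penalty.
#'
#' @param pe a \code{\linkS4class{PerturbationExperiment}} (replicates
#'   are mean-summarized if present), or an observation matrix.
#' @param Z design matrix (ignored when \code{pe} is a
#'   \code{PerturbationExperiment}).
#' @param theta thresholds (ditto).
#' @param config an \code{\linkS4class{InferenceConfig}}.
#' @param activations,inhibitions optional prior edges, see
#'   \code{\link{addEdgePriors}}.
#' @param sources,sinks optional node sets, see
#'   \code{\link{addSourceSinkConstraints}}.
#' @return an \code{\linkS4class{InferenceResult}}.
#' @export
inferNetwork <- function(pe, Z = NULL, theta = NULL,
                         config = inferenceConfig(),
                         activations = NULL, inhibitions = NULL,
                         sources = NULL, sinks = NULL) {
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
  X <- discretizeObservations(D, theta)
  spec <- buildLP(X, D, Z, theta, config)
  if (!is.null(activations) || !is.null(inhibitions))
    spec <- addEdgePriors(spec, activations, inhibitions, config)
  if (!is.null(sources) || !is.null(sinks))
    spec <- addSourceSinkConstraints(spec, sources %||% character(),
                                     sinks %||% character(), config)
  solveLP(spec, config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
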