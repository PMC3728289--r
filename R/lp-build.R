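# Assembly of the inference linear program.
#
# For every (gene i, experiment k) with the gene observed and not
# directly targeted, the discretized state dictates one constraint on
# the incoming weights of i:
#   active:   sum_j a_jk (w+_ji - w-_ji) + b+_i - b-_i >= theta_i + eps
#   inactive: sum_j a_jk (w+_ji - w-_ji) + b+_i - b-_i - xi_ik
#                                                    <= theta_i - eps
# Parent values a_jk are 0 for genes silenced in experiment k and
# otherwise the parent's discretized state (or raw observation in
# continuous mode). A missing parent value takes its worst case: 0 in
# active constraints, 1 in inactive ones. The objective is the L1 norm
# of weights and biases plus a penalized slack total; minimizing it
# drives the solution towards the sparsest network consistent with the
# perturbation responses.

#' Assemble the network-inference linear program
#'
#' @param X binary experiment x gene state matrix (NA = missing), e.g.
#'   from \code{\link{discretizeObservations}}.
#' @param D experiment x gene observation matrix (supplies the slack cap
#'   via its variance, and parent values in continuous mode).
#' @param Z binary experiment x gene knockdown design.
#' @param theta positive per-gene thresholds.
#' @param config an \code{\linkS4class{InferenceConfig}}.
#' @return an \code{\linkS4class{LPSpec}}.
#' @examples
#' sim <- simulateScreen(simulationConfig(nNodes = 4, nEdges = 4, seed = 1))
#' pe <- summarizeReplicates(sim$data)
#' D <- observationMatrix(pe)
#' X <- discretizeObservations(D, activationThresholds(pe))
#' buildLP(X, D, designMatrix(pe), activationThresholds(pe))
#' @export
buildLP <- function(X, D, Z, theta, config = inferenceConfig()) {
  X <- as.matrix(X); D <- as.matrix(D); Z <- as.matrix(Z)
  m <- nrow(Z); n <- ncol(Z)
  if (!all(dim(X) == c(m, n)) || !all(dim(D) == c(m, n)))
    stop("X, D and Z must share the same experiment x gene shape")
  if (!all(Z %in% c(0, 1))) stop("design Z must be binary")
  theta <- .checkTheta(theta, colnames(Z))
  theta <- rep_len(theta, n)
  genes <- colnames(Z)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  exps <- rownames(Z)
  if (is.null(exps)) exps <- paste0("exp", seq_len(m))
  eps <- config@epsilon

  # variable layout: per gene i the block [w+_.i, w-_.i, b+_i, b-_i],
  # then all xi variables
  nw <- n - 1L
  blockSize <- 2L * nw + 2L
  varName <- character(n * blockSize)
  varTag <- character(n * blockSize)
  varGene <- integer(n * blockSize)
  for (i in seq_len(n)) {
    par <- genes[-i]
    off <- (i - 1L) * blockSize
    varName[off + seq_len(2L * nw + 2L)] <-
      c(paste0("wp_", par, "_", genes[i]), paste0("wm_", par, "_", genes[i]),
        paste0("bp_", genes[i]), paste0("bm_", genes[i]))
    varTag[off + seq_len(2L * nw + 2L)] <-
      c(rep("w+", nw), rep("w-", nw), "b+", "b-")
    varGene[off + seq_len(2L * nw + 2L)] <- i
  }

  observed <- !is.na(X)
  slackCells <- which(Z == 0 & observed & X == 0, arr.ind = TRUE)
  nXi <- nrow(slackCells)
  if (nXi) {
    varName <- c(varName, paste0("xi_", genes[slackCells[, 2L]], "_",
                                 exps[slackCells[, 1L]]))
    varTag <- c(varTag, rep("xi", nXi))
    varGene <- c(varGene, as.integer(slackCells[, 2L]))
  }
  nv <- length(varName)

  # objective
  obj <- numeric(nv)
  obj[varTag %in% c("w+", "w-", "b+", "b-")] <- 1
  if (nXi)
    obj[varTag == "xi"] <-
      if (config@normalizeSlack) config@lambda / nXi else config@lambda

  # bounds: the slack cap scales with the data variance, floored at
  # 2*epsilon so that any direct active/inactive contradiction stays
  # absorbable and the program is always feasible (w = 0, b = theta +
  # epsilon, xi = 2*epsilon is a feasible point)
  varD <- var(as.numeric(D[!is.na(D)]))
  if (!is.finite(varD)) varD <- 0
  cap <- max(config@slackCapFactor * varD, 2 * eps)
  upper <- rep(Inf, nv)
  if (nXi) upper[varTag == "xi"] <- cap

  # constraints, triplet form
  cells <- which(Z == 0 & observed, arr.ind = TRUE)
  if (!nrow(cells))
    warning("no usable (gene, experiment) cells: constraint set is empty")
  xiIndex <- matrix(0L, m, n)
  if (nXi) xiIndex[slackCells] <- n * blockSize + seq_len(nXi)

  ti <- ri <- vi <- vector("list", nrow(cells))
  dirs <- character(nrow(cells))
  rhs <- numeric(nrow(cells))
  conTag <- character(nrow(cells))
  conGene <- integer(nrow(cells))
  refine <- numeric(nv)
  parentVals <- if (config@parentValueMode == "discretized") X else D
  for (cc in seq_len(nrow(cells))) {
    k <- cells[cc, 1L]; i <- cells[cc, 2L]
    act <- X[k, i] == 1
    a <- parentVals[k, -i]
    a[Z[k, -i] == 1] <- 0
    a[is.na(a)] <- if (act) 0 else 1
    off <- (i - 1L) * blockSize
    cols <- c(off + seq_len(nw),            # w+
              off + nw + seq_len(nw),       # w-
              off + 2L * nw + 1:2)          # b+, b-
    vals <- c(a, -a, 1, -1)
    if (!act && xiIndex[k, i]) {
      cols <- c(cols, xiIndex[k, i])
      vals <- c(vals, -1)
    }
    keep <- vals != 0
    ti[[cc]] <- rep.int(cc, sum(keep))
    ri[[cc]] <- cols[keep]
    vi[[cc]] <- vals[keep]
    dirs[cc] <- if (act) ">=" else "<="
    rhs[cc] <- if (act) theta[i] + eps else theta[i] - eps
    conTag[cc] <- if (act) "active" else "inactive"
    conGene[cc] <- i
    # tie-break bookkeeping: variables contradicted by this cell
    active_parents <- which(a > 0)
    if (act) {
      refine[off + nw + active_parents] <-
        refine[off + nw + active_parents] + 1    # w- against active child
      refine[off + 2L * nw + 2L] <- refine[off + 2L * nw + 2L] + 1  # b-
    } else {
      refine[off + active_parents] <-
        refine[off + active_parents] + 1         # w+ against inactive child
      refine[off + 2L * nw + 1L] <- refine[off + 2L * nw + 1L] + 1  # b+
    }
  }
  A <- Matrix::sparseMatrix(i = as.integer(unlist(ti)),
                            j = as.integer(unlist(ri)),
                            x = as.numeric(unlist(vi)),
                            dims = c(nrow(cells), nv))
  names(obj) <- varName
  new("LPSpec", nodes = genes, objective = obj, A = A, dir = dirs,
      rhs = rhs, upper = upper, varTag = varTag,
      varGene = as.integer(varGene), conTag = conTag, conGene = conGene,
      nInactive = as.integer(nXi), refine = refine)
}

.edgeCols <- function(spec, from, to) {
  # column indices of (w+, w-) for the ordered edge from -> to
  wp <- match(paste0("wp_", from, "_", to), names(spec@objective))
  wm <- match(paste0("wm_", from, "_", to), names(spec@objective))
  c(wp, wm)
}

.appendConstraints <- function(spec, rows, dir, rhs, tag, gene) {
  spec@A <- rbind(spec@A, rows)
  spec@dir <- c(spec@dir, dir)
  spec@rhs <- c(spec@rhs, rhs)
  spec@conTag <- c(spec@conTag, tag)
  spec@conGene <- c(spec@conGene, as.integer(gene))
  spec
}

#' Constrain known edges to be present
#'
#' Known activations j -> i append \code{w+_ji - w-_ji >= priorEdgeMin};
#' known inhibitions append \code{w+_ji - w-_ji <= -priorEdgeMin},
#' forcing the edge into the reconstruction with at least that
#' magnitude.
#'
#' @param spec an \code{\linkS4class{LPSpec}}.
#' @param activations,inhibitions two-column matrices or data.frames of
#'   (source, target) node labels; NULL for none.
#' @param config an \code{\linkS4class{InferenceConfig}} (supplies
#'   \code{priorEdgeMin}).
#' @return the augmented \code{LPSpec}.
#' @export
addEdgePriors <- function(spec, activations = NULL, inhibitions = NULL,
                          config = inferenceConfig()) {
  addOne <- function(spec, from, to, sign) {
    if (from == to) stop("prior on a self-loop (", from, ") is not allowed")
    if (!all(c(from, to) %in% spec@nodes))
      stop("prior edge references unknown node(s): ", from, " -> ", to)
    cols <- .edgeCols(spec, from, to)
    row <- Matrix::sparseMatrix(i = c(1L, 1L), j = cols, x = c(1, -1),
                                dims = c(1L, length(spec@objective)))
    .appendConstraints(spec, row,
                       dir = if (sign > 0) ">=" else "<=",
                       rhs = sign * config@priorEdgeMin,
                       tag = "prior_edge",
                       gene = match(to, spec@nodes))
  }
  normalize <- function(x) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    if (ncol(x) < 2L) stop("prior edges need (source, target) columns")
    x
  }
  activations <- normalize(activations)
  inhibitions <- normalize(inhibitions)
  if (!is.null(activations))
    for (r in seq_len(nrow(activations)))
      spec <- addOne(spec, activations[r, 1L], activations[r, 2L], 1)
  if (!is.null(inhibitions))
    for (r in seq_len(nrow(inhibitions)))
      spec <- addOne(spec, inhibitions[r, 1L], inhibitions[r, 2L], -1)
  spec
}

#' Require in/out edges for non-source/non-sink nodes
#'
#' When receptor (source) and terminal (sink) identities are known,
#' every non-source node must carry at least one incoming edge and
#' every non-sink node at least one outgoing edge, expressed as a
#' minimal absolute-weight degree:
#' \code{sum_j (w+_ji + w-_ji) >= degreeDelta} (incoming, i not a
#' source) and \code{sum_j (w+_ij + w-_ij) >= degreeDelta} (outgoing,
#' i not a sink). A node declared both source and sink receives no
#' constraint.
#'
#' @param spec an \code{\linkS4class{LPSpec}}.
#' @param sources,sinks character vectors of node labels.
#' @param config an \code{\linkS4class{InferenceConfig}} (supplies
#'   \code{degreeDelta}).
#' @return the augmented \code{LPSpec}.
#' @export
addSourceSinkConstraints <- function(spec, sources = character(),
                                     sinks = character(),
                                     config = inferenceConfig()) {
  bad <- setdiff(c(sources, sinks), spec@nodes)
  if (length(bad)) stop("unknown source/sink node(s): ",
                        paste(bad, collapse = ", "))
  nv <- length(spec@objective)
  for (i in seq_along(spec@nodes)) {
    node <- spec@nodes[i]
    if (!node %in% sources) {  # require incoming edge weight mass
      cols <- which(spec@varGene == i & spec@varTag %in% c("w+", "w-"))
      row <- Matrix::sparseMatrix(i = rep(1L, length(cols)), j = cols,
                                  x = rep(1, length(cols)),
                                  dims = c(1L, nv))
      spec <- .appendConstraints(spec, row, ">=", config@degreeDelta,
                                 "degree_in", i)
    }
    if (!node %in% sinks) {    # require outgoing edge weight mass
      cols <- unlist(lapply(setdiff(seq_along(spec@nodes), i), function(tg)
        .edgeCols(spec, node, spec@nodes[tg])))
      row <- Matrix::sparseMatrix(i = rep(1L, length(cols)), j = cols,
                                  x = rep(1, length(cols)),
                                  dims = c(1L, nv))
      spec <- .appendConstraints(spec, row, ">=", config@degreeDelta,
                                 "degree_out", NA_integer_)
    }
  }
  spec
}
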