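#' Construct a PerturbationExperiment
#'
#' Bundles continuous activity measurements with the binary knockdown
#' design and per-gene activation thresholds. Matrices follow the
#' experiment-major convention used throughout the package: rows are
#' perturbation experiments, columns are genes. Replicated data are
#' passed as a list of observation matrices (one per replicate), all
#' sharing the design.
#'
#' @param observations numeric experiment x gene matrix (NA = missing),
#'   or a list of such matrices, one per replicate.
#' @param design binary experiment x gene matrix; 1 marks a gene
#'   targeted by the experiment's knockdown.
#' @param theta positive per-gene activation thresholds (recycled if
#'   scalar).
#' @param trueStates optional experiment x gene binary matrix (or list,
#'   as \code{observations}) of simulator ground-truth states.
#' @return a \code{\linkS4class{PerturbationExperiment}} with one column
#'   per (experiment, replicate) pair.
#' @examples
#' D <- matrix(runif(6), 2, 3, dimnames = list(c("e1","e2"), c("a","b","c")))
#' Z <- matrix(0, 2, 3, dimnames = dimnames(D)); Z[1, 1] <- 1
#' pe <- PerturbationExperiment(D, Z, theta = 0.6)
#' observationMatrix(pe)
#' @export
PerturbationExperiment <- function(observations, design, theta = 0.6,
                                   trueStates = NULL) {
  if (!is.list(observations)) observations <- list(observations)
  if (!is.null(trueStates) && !is.list(trueStates))
    trueStates <- list(trueStates)
  design <- as.matrix(design)
  m <- nrow(design); n <- ncol(design)
  shapes <- vapply(observations, function(o) all(dim(o) == c(m, n)), TRUE)
  if (!all(shapes))
    stop("replicate observation matrices must all match the design shape (",
         m, " x ", n, ")")
  genes <- colnames(design)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  exps <- rownames(design)
  if (is.null(exps)) exps <- paste0("exp", seq_len(m))
  nr <- length(observations)

  # genes x (experiment * replicate), replicate-major within experiment
  act <- do.call(cbind, lapply(seq_len(m), function(k)
    vapply(seq_len(nr), function(r) as.numeric(observations[[r]][k, ]),
           numeric(n))))
  kd <- do.call(cbind, lapply(seq_len(m), function(k)
    matrix(rep(as.numeric(design[k, ]), nr), nrow = n)))
  cd <- S4Vectors::DataFrame(
    experiment = rep(exps, each = nr),
    replicate = rep.int(seq_len(nr), m))
  assays <- list(activity = act, knockdown = kd)
  if (!is.null(trueStates))
    assays$trueState <- do.call(cbind, lapply(seq_len(m), function(k)
      vapply(seq_len(nr), function(r) as.numeric(trueStates[[r]][k, ]),
             numeric(n))))
  assays <- lapply(assays, function(a) {
    dimnames(a) <- list(genes, paste(cd$experiment, cd$replicate, sep = "."))
    a
  })
  se <- SummarizedExperiment(
    assays = assays, colData = cd,
    rowData = S4Vectors::DataFrame(
      theta = rep_len(as.numeric(theta), n), row.names = genes))
  new("PerturbationExperiment", se)
}

#' @rdname PerturbationExperiment-class
#' @param x a \code{PerturbationExperiment} with one replicate per
#'   experiment (summarize replicates first otherwise).
#' @export
setMethod("observationMatrix", "PerturbationExperiment", function(x) {
  .assertUnreplicated(x)
  D <- t(assay(x, "activity"))
  rownames(D) <- colData(x)$experiment
  D
})

#' @rdname PerturbationExperiment-class
#' @export
setMethod("designMatrix", "PerturbationExperiment", function(x) {
  cd <- colData(x)
  first <- !duplicated(cd$experiment)
  Z <- t(assay(x, "knockdown")[, first, drop = FALSE])
  rownames(Z) <- cd$experiment[first]
  Z
})

#' @rdname PerturbationExperiment-class
#' @export
setMethod("activationThresholds", "PerturbationExperiment", function(x)
  setNames(rowData(x)$theta, rownames(x)))

.assertUnreplicated <- function(x) {
  if (anyDuplicated(colData(x)$experiment))
    stop("multiple replicates per experiment present; ",
         "call summarizeReplicates() first")
  invisible(x)
}

#' Collapse replicate measurements
#'
#' Summarizes the replicate columns of each experiment into a single
#' value per (experiment, gene) cell, ignoring missing replicates. The
#' arithmetic mean is the default (the convention for simulated
#' screens); the median is selectable (the convention for flow-cytometry
#' style data). Cells with all replicates missing stay missing.
#'
#' @param x a \code{\linkS4class{PerturbationExperiment}}.
#' @param method "mean" or "median".
#' @return a \code{PerturbationExperiment} with one column per
#'   experiment.
#' @examples
#' D1 <- matrix(c(0.9, 0.1), 1, 2); D2 <- matrix(c(1.1, 0.3), 1, 2)
#' Z <- matrix(0, 1, 2)
#' pe <- PerturbationExperiment(list(D1, D2), Z)
#' observationMatrix(summarizeReplicates(pe))
#' @export
summarizeReplicates <- function(x, method = c("mean", "median")) {
  method <- match.arg(method)
  fun <- if (method == "mean") {
    function(v) mean(v, na.rm = TRUE)
  } else {
    function(v) median(v, na.rm = TRUE)
  }
  cd <- colData(x)
  exps <- unique(cd$experiment)
  act <- assay(x, "activity")
  out <- vapply(exps, function(e) {
    cols <- which(cd$experiment == e)
    apply(act[, cols, drop = FALSE], 1L, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else fun(v)
    })
  }, numeric(nrow(x)))
  first <- !duplicated(cd$experiment)
  kd <- assay(x, "knockdown")[, first, drop = FALSE]
  dimnames(out) <- list(rownames(x), exps)
  colnames(kd) <- exps
  assays <- list(activity = out, knockdown = kd)
  if ("trueState" %in% assayNames(x)) {
    ts <- assay(x, "trueState")[, first, drop = FALSE]
    colnames(ts) <- exps
    assays$trueState <- ts
  }
  se <- SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(experiment = exps,
                                   replicate = rep(1L, length(exps)),
                                   row.names = exps),
    rowData = rowData(x))
  new("PerturbationExperiment", se)
}
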