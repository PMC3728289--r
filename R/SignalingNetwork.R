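#' Construct a SignalingNetwork
#'
#' @param weights square numeric matrix; \code{weights[j, i]} is the
#'   signed influence of node \code{j} on node \code{i}. Row/column
#'   names, when present, name the nodes.
#' @param bias numeric baseline activity per node (recycled if scalar).
#' @param nodes node labels; defaults to the dimnames of \code{weights}.
#' @param sources,sinks optional character vectors of receptor-like and
#'   terminal nodes.
#' @return a \code{\linkS4class{SignalingNetwork}}.
#' @examples
#' w <- matrix(0, 3, 3, dimnames = list(c("s","a","t"), c("s","a","t")))
#' w["s","a"] <- 1; w["a","t"] <- 1
#' net <- SignalingNetwork(w, bias = c(0.95, 0, 0), sources = "s", sinks = "t")
#' nodeLabels(net)
#' @export
SignalingNetwork <- function(weights, bias = 0, nodes = rownames(weights),
                             sources = character(), sinks = character()) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (is.null(nodes)) nodes <- paste0("g", seq_len(n))
  dimnames(weights) <- list(nodes, nodes)
  bias <- rep_len(as.numeric(bias), n)
  names(bias) <- nodes
  new("SignalingNetwork", nodes = as.character(nodes), weights = weights,
      bias = bias, sources = as.character(sources),
      sinks = as.character(sinks))
}

#' @rdname SignalingNetwork-class
#' @export
setMethod("nodeLabels", "SignalingNetwork", function(x) x@nodes)

#' @rdname SignalingNetwork-class
#' @export
setMethod("edgeWeights", "SignalingNetwork", function(x) x@weights)

#' @rdname SignalingNetwork-class
#' @export
setMethod("biasTerms", "SignalingNetwork", function(x) x@bias)

#' @rdname SignalingNetwork-class
#' @export
setMethod("sourceNodes", "SignalingNetwork", function(x) x@sources)

#' @rdname SignalingNetwork-class
#' @export
setMethod("sinkNodes", "SignalingNetwork", function(x) x@sinks)

#' @rdname SignalingNetwork-class
#' @export
setMethod("edgeTable", "SignalingNetwork", function(x) {
  idx <- which(x@weights != 0, arr.ind = TRUE)
  df <- data.frame(source = x@nodes[idx[, 1L]],
                   target = x@nodes[idx[, 2L]],
                   weight = x@weights[idx],
                   stringsAsFactors = FALSE)
  df[order(df$source, df$target), , drop = FALSE]
})

setMethod("show", "SignalingNetwork", function(object) {
  w <- object@weights
  cat("SignalingNetwork with", length(object@nodes), "nodes and",
      sum(w != 0), "edges (", sum(w > 0), "activating,",
      sum(w < 0), "inhibiting )\n")
  if (length(object@sources))
    cat("  sources:", paste(object@sources, collapse = ", "), "\n")
  if (length(object@sinks))
    cat("  sinks:  ", paste(object@sinks, collapse = ", "), "\n")
})

setMethod("show", "InferenceResult", function(object) {
  cat("InferenceResult (status:", object@status, ")\n")
  cat("  objective:", format(object@objectiveValue, digits = 6), "\n")
  cat("  inferred edges:", sum(object@network@weights != 0), "\n")
  cat("  non-zero slacks:", nrow(object@slacks), "\n")
})

setMethod("show", "LPSpec", function(object) {
  cat("LPSpec:", length(object@objective), "variables,",
      nrow(object@A), "constraints,", object@nInactive,
      "slack variables\n")
  cat("  variables:", paste(sprintf("%s=%d", names(tv <- table(object@varTag)),
                                    tv), collapse = " "), "\n")
  if (nrow(object@A))
    cat("  constraints:", paste(sprintf("%s=%d",
        names(tc <- table(object@conTag)), tc), collapse = " "), "\n")
})

setMethod("show", "CVResult", function(object) {
  cat("CVResult: best lambda =", object@bestLambda, "\n")
  cat("  grid:", paste(object@lambdaGrid, collapse = ", "), "\n")
  cat("  mean MSE by lambda:",
      paste(format(rowMeans(object@mseTable, na.rm = TRUE), digits = 4),
            collapse = ", "), "\n")
})

setMethod("show", "EdgeSummary", function(object) {
  cat("EdgeSummary:", sum(object@keepMask != 0), "edges kept of",
      sum(object@medianWeight != 0), "with non-zero median\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (mode:", object@mode, ")\n")
  cat(sprintf("  TP=%g TN=%g FP=%g FN=%g\n",
              object@tp, object@tn, object@fp, object@fn))
  cat(sprintf("  SP=%.2f SN=%.2f PR=%.2f AC=%.2f\n",
              object@sp, object@sn, object@pr, object@ac))
  if (!is.na(object@aucRoc))
    cat(sprintf("  AUC-ROC=%.3f AUC-PR=%.3f\n", object@aucRoc, object@aucPr))
  if (length(object@pValues))
    cat("  p-values:", paste(sprintf("%s=%.3g", names(object@pValues),
                                     object@pValues), collapse = " "), "\n")
})

#' Configuration constructors
#'
#' \code{inferenceConfig} and \code{simulationConfig} build validated
#' parameter objects; see \code{\linkS4class{InferenceConfig}} and
#' \code{\linkS4class{SimulationConfig}} for the meaning and defaults of
#' every field.
#'
#' @param ... named fields overriding the defaults.
#' @return an \code{InferenceConfig} or \code{SimulationConfig}.
#' @examples
#' inferenceConfig(lambda = 0.5)
#' simulationConfig(nNodes = 10, nEdges = 7, seed = 3)
#' @export
inferenceConfig <- function(...) {
  do.call(new, c(list("InferenceConfig"), list(...)))
}

#' @rdname inferenceConfig
#' @export
simulationConfig <- function(...) {
  args <- list(...)
  for (f in c("nNodes", "nEdges", "nDoubleKnockdowns", "nReplicates", "seed"))
    if (!is.null(args[[f]])) args[[f]] <- as.integer(args[[f]])
  do.call(new, c(list("SimulationConfig"), args))
}
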