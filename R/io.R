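# File formats. Everything is plain TSV with a header row and "NA" for
# missing values; SIF is supported for interoperability with network
# viewers. Observation tables may be wide (one row per experiment) or
# long (an extra replicate column).

#' Read / write networks
#'
#' Edge-list TSV has columns (source, target, weight); SIF lines read
#' \code{source<TAB>activates|inhibits<TAB>target} with the magnitude in
#' an optional fourth column (default 1). Duplicate edges, self-loops
#' and (for \code{readNetwork} with \code{nodes} given) unknown nodes
#' are rejected with line numbers. A write-then-read round trip
#' reproduces the edge set.
#'
#' @param path file path.
#' @param format "edge_tsv" or "sif".
#' @param nodes optional complete node set (isolated nodes are kept).
#' @return \code{readNetwork}: a
#'   \code{\linkS4class{SignalingNetwork}}.
#' @export
readNetwork <- function(path, format = c("edge_tsv", "sif"), nodes = NULL) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("source", "target", "weight") %in% names(df)))
      stop("edge TSV needs columns source, target, weight: ", path)
    src <- as.character(df$source); tgt <- as.character(df$target)
    w <- as.numeric(df$weight)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 0L) < 3L)
    if (length(bad))
      stop("malformed SIF line(s) ", paste(bad, collapse = ", "),
           " in ", path)
    src <- vapply(parts, `[`, "", 1L)
    rel <- vapply(parts, `[`, "", 2L)
    tgt <- vapply(parts, `[`, "", 3L)
    if (!all(rel %in% c("activates", "inhibits")))
      stop("SIF relation must be 'activates' or 'inhibits'; offending ",
           "line(s): ",
           paste(which(!rel %in% c("activates", "inhibits")),
                 collapse = ", "))
    mag <- vapply(parts, function(p)
      if (length(p) >= 4L) as.numeric(p[4L]) else 1, 0)
    w <- ifelse(rel == "activates", mag, -mag)
  }
  bad <- which(is.na(w) | !nzchar(src) | !nzchar(tgt))
  if (length(bad))
    stop("malformed row(s) ", paste(bad, collapse = ", "), " in ", path)
  loops <- which(src == tgt)
  if (length(loops))
    stop("self-loop(s) at line(s) ", paste(loops, collapse = ", "),
         " in ", path)
  dup <- which(duplicated(paste(src, tgt)))
  if (length(dup))
    stop("duplicate edge(s) at line(s) ", paste(dup, collapse = ", "),
         " in ", path)
  if (is.null(nodes)) nodes <- sort(unique(c(src, tgt)))
  unknown <- which(!(src %in% nodes) | !(tgt %in% nodes))
  if (length(unknown))
    stop("unknown node(s) at line(s) ", paste(unknown, collapse = ", "),
         " in ", path)
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  W[cbind(src, tgt)] <- w
  SignalingNetwork(W, nodes = nodes)
}

#' @rdname readNetwork
#' @param net a \code{\linkS4class{SignalingNetwork}}.
#' @export
writeNetwork <- function(net, path, format = c("edge_tsv", "sif")) {
  format <- match.arg(format)
  et <- edgeTable(net)
  if (format == "edge_tsv") {
    write.table(et, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    rel <- ifelse(et$weight > 0, "activates", "inhibits")
    writeLines(paste(et$source, rel, et$target, abs(et$weight),
                     sep = "\t"), path)
  }
  invisible(path)
}

#' Read / write the per-node annotation table
#'
#' TSV with columns (node, bias, theta, is_source, is_sink).
#'
#' @param path file path.
#' @return \code{readNodeTable}: data.frame with those columns.
#' @export
readNodeTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("node", "bias", "theta", "is_source", "is_sink")
  if (!all(need %in% names(df)))
    stop("node table needs columns ", paste(need, collapse = ", "))
  df
}

#' @rdname readNodeTable
#' @param net a \code{\linkS4class{SignalingNetwork}}.
#' @param theta per-gene thresholds.
#' @export
writeNodeTable <- function(net, theta, path) {
  df <- data.frame(node = net@nodes, bias = net@bias,
                   theta = rep_len(as.numeric(theta), length(net@nodes)),
                   is_source = as.integer(net@nodes %in% net@sources),
                   is_sink = as.integer(net@nodes %in% net@sinks))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read observation and design tables
#'
#' Both tables are TSV with the experiment id in the first column
#' (named \code{experiment}) and one column per gene; the observation
#' table may additionally carry a \code{replicate} column (long
#' format). Columns are aligned to the design by header name, not by
#' position. "NA" marks missing observations; design entries must be
#' 0/1.
#'
#' @param obsPath,designPath file paths.
#' @param theta per-gene thresholds for the returned container.
#' @return a \code{\linkS4class{PerturbationExperiment}}.
#' @export
readPerturbationTables <- function(obsPath, designPath, theta = 0.6) {
  obs <- read.delim(obsPath, stringsAsFactors = FALSE, check.names = FALSE)
  des <- read.delim(designPath, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (names(obs)[1L] != "experiment" || names(des)[1L] != "experiment")
    stop("first column of both tables must be 'experiment'")
  genes <- setdiff(names(des), "experiment")
  hasRep <- "replicate" %in% names(obs)
  obsGenes <- setdiff(names(obs), c("experiment", "replicate"))
  if (!setequal(genes, obsGenes))
    stop("gene columns differ between observations and design: ",
         paste(union(setdiff(genes, obsGenes), setdiff(obsGenes, genes)),
               collapse = ", "))
  Z <- as.matrix(des[genes])
  if (!all(Z %in% c(0, 1))) stop("design entries must be 0 or 1")
  rownames(Z) <- des$experiment
  exps <- des$experiment
  if (!setequal(exps, unique(obs$experiment)))
    stop("experiment ids differ between observations and design")
  reps <- if (hasRep) sort(unique(obs$replicate)) else 1L
  mats <- lapply(reps, function(r) {
    sub <- if (hasRep) obs[obs$replicate == r, , drop = FALSE] else obs
    M <- matrix(NA_real_, length(exps), length(genes),
                dimnames = list(exps, genes))
    M[cbind(rep(match(sub$experiment, exps), times = length(genes)),
            rep(seq_along(genes), each = nrow(sub)))] <-
      as.numeric(unlist(sub[genes]))
    M
  })
  PerturbationExperiment(mats, Z, theta = theta)
}

#' Write observations (long format) and design tables
#'
#' @param pe a \code{\linkS4class{PerturbationExperiment}}.
#' @param obsPath,designPath output paths.
#' @export
writePerturbationTables <- function(pe, obsPath, designPath) {
  cd <- colData(pe)
  act <- t(assay(pe, "activity"))
  df <- data.frame(experiment = cd$experiment, replicate = cd$replicate,
                   act, check.names = FALSE)
  write.table(df, obsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  Z <- designMatrix(pe)
  write.table(data.frame(experiment = rownames(Z), Z, check.names = FALSE),
              designPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(obsPath, designPath))
}

#' Serialize a linear program in CPLEX-LP text format
#'
#' Debug aid: writes the objective, constraints and bounds of an
#' assembled program in the LP-file dialect understood by most solvers.
#'
#' @param spec an \code{\linkS4class{LPSpec}}.
#' @param path output path.
#' @export
writeLPFormat <- function(spec, path) {
  nm <- names(spec@objective)
  term <- function(coef, var) {
    sprintf("%s %g %s", ifelse(coef < 0, "-", "+"), abs(coef), var)
  }
  con <- file(path, "w")
  on.exit(close(con))
  nz <- which(spec@objective != 0)
  writeLines("Minimize", con)
  writeLines(paste(" obj:",
                   paste(term(spec@objective[nz], nm[nz]), collapse = " ")),
             con)
  writeLines("Subject To", con)
  At <- as(spec@A, "TsparseMatrix")
  for (r in seq_along(spec@rhs)) {
    sel <- which(At@i == r - 1L)
    lhs <- paste(term(At@x[sel], nm[At@j[sel] + 1L]), collapse = " ")
    op <- c("<=" = "<=", ">=" = ">=", "=" = "=")[spec@dir[r]]
    writeLines(sprintf(" c%d_%s: %s %s %g", r, spec@conTag[r], lhs, op,
                       spec@rhs[r]), con)
  }
  writeLines("Bounds", con)
  fin <- which(is.finite(spec@upper))
  for (j in fin)
    writeLines(sprintf(" 0 <= %s <= %g", nm[j], spec@upper[j]), con)
  writeLines("End", con)
  invisible(path)
}

#' Export results as JSON
#'
#' \code{InferenceResult}: weights as an edge list plus bias, slacks,
#' status and objective. \code{EvaluationReport}: counts, metrics,
#' AUCs and p-values. \code{CVResult}: grid, MSE table and best
#' penalty. \code{EdgeSummary}: median/MAD edge list.
#'
#' @param x a supported result object.
#' @param path output path.
#' @param seed optional seed recorded alongside the payload.
#' @export
resultToJSON <- function(x, path, seed = NULL) {
  payload <- if (is(x, "InferenceResult")) {
    list(status = x@status, objective = x@objectiveValue,
         edges = edgeTable(x@network), bias = as.list(x@network@bias),
         slacks = x@slacks)
  } else if (is(x, "EvaluationReport")) {
    list(mode = x@mode,
         counts = list(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn),
         metrics = list(sp = x@sp, sn = x@sn, pr = x@pr, ac = x@ac),
         auc = list(roc = x@aucRoc, pr = x@aucPr),
         p_values = as.list(x@pValues))
  } else if (is(x, "CVResult")) {
    list(best_lambda = x@bestLambda, grid = x@lambdaGrid,
         mse = x@mseTable, seed = x@seed)
  } else if (is(x, "EdgeSummary")) {
    idx <- which(x@keepMask != 0, arr.ind = TRUE)
    list(edges = data.frame(
      source = rownames(x@medianWeight)[idx[, 1L]],
      target = colnames(x@medianWeight)[idx[, 2L]],
      median = x@medianWeight[idx], mad = x@madWeight[idx]))
  } else stop("unsupported object of class ", class(x))
  payload$package_version <- as.character(packageVersion("perturbLP"))
  if (!is.null(seed)) payload$seed <- seed
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
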