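# Scoring of inferred topologies against a reference: confusion
# metrics over ordered node pairs (with a relaxed REP mode crediting
# reversed and path-mediated edges), ROC / precision-recall areas,
# three-class signed evaluation, permutation baselines and reachability
# utilities.

.adjacency <- function(x) {
  if (is(x, "SignalingNetwork")) x@weights else as.matrix(x)
}

.offDiagMask <- function(n) {
  m <- matrix(TRUE, n, n)
  diag(m) <- FALSE
  m
}

#' Confusion metrics from raw counts
#'
#' Builds an \code{\linkS4class{EvaluationReport}} directly from
#' TP/TN/FP/FN counts: specificity tn/(tn+fp), sensitivity tp/(tp+fn),
#' precision tp/(tp+fp), accuracy (tp+tn)/total, reported to two
#' decimals (half away from zero).
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @param mode label recorded in the report.
#' @return an \code{\linkS4class{EvaluationReport}}.
#' @examples
#' metricsFromCounts(3, 95, 9, 14)  # SP 0.91, SN 0.18, PR 0.25, AC 0.81
#' @export
metricsFromCounts <- function(tp, tn, fp, fn, mode = "directed") {
  rate <- function(num, den)
    if (den == 0) NA_real_ else roundHalfUp(num / den, 2L)
  new("EvaluationReport", tp = tp, tn = tn, fp = fp, fn = fn,
      sp = rate(tn, tn + fp), sn = rate(tp, tp + fn),
      pr = rate(tp, tp + fp), ac = rate(tp + tn, tp + tn + fp + fn),
      aucRoc = NA_real_, aucPr = NA_real_,
      pValues = setNames(numeric(), character()), mode = mode)
}

#' Score a predicted network against a reference
#'
#' Mode \code{"directed"} compares ordered off-diagonal pairs: a pair is
#' positive in the reference iff it carries an edge. Mode
#' \code{"unsigned"} does the same on unordered pairs (an edge in either
#' direction counts, for undirected/unsigned references). Mode
#' \code{"rep"} relaxes the directed comparison: a predicted edge (a,b)
#' is credited when the reference contains (a,b), (b,a) or a directed
#' path from a to b; symmetrically, a reference edge counts as found
#' when some predicted edge matches it under the same relaxed rule, so
#' it is not double-counted as a false negative.
#'
#' @param pred,ref \code{\linkS4class{SignalingNetwork}}s or adjacency
#'   matrices over the same node set.
#' @param mode "directed", "rep" or "unsigned".
#' @return an \code{\linkS4class{EvaluationReport}}.
#' @export
confusionMetrics <- function(pred, ref,
                             mode = c("directed", "rep", "unsigned")) {
  mode <- match.arg(mode)
  P <- .adjacency(pred); R <- .adjacency(ref)
  if (!is.null(rownames(P)) && !is.null(rownames(R))) {
    if (!setequal(rownames(P), rownames(R))) {
      d <- union(setdiff(rownames(P), rownames(R)),
                 setdiff(rownames(R), rownames(P)))
      stop("node sets differ; symmetric difference: ",
           paste(d, collapse = ", "))
    }
    R <- R[rownames(P), rownames(P)]
  }
  if (!all(dim(P) == dim(R))) stop("prediction and reference shape differ")
  n <- nrow(P)
  off <- .offDiagMask(n)
  if (mode == "directed") {
    p <- (P != 0)[off]; r <- (R != 0)[off]
    tp <- sum(p & r); fp <- sum(p & !r)
    fn <- sum(!p & r); tn <- sum(!p & !r)
  } else if (mode == "unsigned") {
    up <- (P != 0) | t(P != 0); ur <- (R != 0) | t(R != 0)
    ut <- upper.tri(P)
    p <- up[ut]; r <- ur[ut]
    tp <- sum(p & r); fp <- sum(p & !r)
    fn <- sum(!p & r); tn <- sum(!p & !r)
  } else {
    reach <- .reachability(R != 0)       # directed path a => b in ref
    relax <- (R != 0) | t(R != 0) | reach
    p <- P != 0; r <- R != 0
    tp <- sum(p & relax & off)
    fp <- sum(p & !relax & off)
    # symmetric rule for the reference side: a reference edge is found
    # when some predicted edge credits it (same pair in either
    # direction, or a predicted path connecting its endpoints)
    found <- r & ((p | t(p)) | .reachability(p))
    fn <- sum(r & !found & off)
    tn <- sum(!p & !relax & off)
  }
  metricsFromCounts(tp, tn, fp, fn, mode = mode)
}

.reachability <- function(adj) {
  # directed reachability (path length >= 1) via iterated boolean product
  A <- (adj != 0) * 1
  n <- nrow(A)
  R <- A
  repeat {
    Rn <- ((R + R %*% A) > 0) * 1
    if (identical(Rn, R)) break
    R <- Rn
  }
  R > 0
}

#' ROC and precision-recall areas for scored edges
#'
#' Scores (typically |median weight|) over all ordered off-diagonal
#' pairs are swept from high to low; tied scores enter simultaneously.
#' The ROC area is the trapezoid area (equivalently the Mann-Whitney
#' statistic with ties counted half); the PR area defaults to step-wise
#' average precision, with trapezoidal interpolation selectable.
#'
#' @param scores numeric matrix (or named vector over ordered pairs) of
#'   edge scores; larger = more confident.
#' @param ref reference network or adjacency matrix; non-zero = edge.
#' @param prMethod "average_precision" or "trapezoid".
#' @return list with \code{aucRoc}, \code{aucPr}, and the swept
#'   \code{curve} (threshold, tp, fp, tpr, fpr, precision, recall).
#' @export
rocPrAuc <- function(scores, ref,
                     prMethod = c("average_precision", "trapezoid")) {
  prMethod <- match.arg(prMethod)
  R <- .adjacency(ref)
  if (is.matrix(scores)) {
    off <- .offDiagMask(nrow(scores))
    s <- scores[off]
    y <- (R != 0)[off]
  } else {
    s <- as.numeric(scores)
    y <- as.logical(R != 0)[seq_along(s)]
  }
  stopifnot(length(s) == length(y))
  nPos <- sum(y); nNeg <- sum(!y)
  if (nPos == 0 || nNeg == 0)
    stop("reference must contain at least one edge and one non-edge")
  thr <- sort(unique(s), decreasing = TRUE)
  tp <- fp <- numeric(length(thr))
  for (t in seq_along(thr)) {
    sel <- s >= thr[t]
    tp[t] <- sum(y[sel]); fp[t] <- sum(!y[sel])
  }
  tpr <- tp / nPos; fpr <- fp / nNeg
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  # sweep starts at the empty prediction (0, 0)
  x <- c(0, fpr); y <- c(0, tpr)
  aucRoc <- sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
  if (prMethod == "average_precision") {
    aucPr <- sum(diff(c(0, tpr)) * prec)
  } else {
    pp <- c(prec[1L], prec)
    aucPr <- sum(diff(c(0, tpr)) * (pp[-1L] + pp[-length(pp)]) / 2)
  }
  list(aucRoc = aucRoc, aucPr = aucPr,
       curve = data.frame(threshold = thr, tp = tp, fp = fp,
                          tpr = tpr, fpr = fpr, precision = prec,
                          recall = tpr))
}

#' Three-class evaluation of signed edge weights
#'
#' Macro-averaged one-vs-rest ROC area over the classes activation
#' (+1), no edge (0) and inhibition (-1). Class-specific scores are the
#' signed weight for activation, its negation for inhibition, and
#' -|weight| for the no-edge class. Classes absent from the reference
#' are skipped (and named in the result).
#'
#' @param weights signed weight matrix (prediction scores).
#' @param ref signed reference: entries in \{-1, 0, +1\}.
#' @return list with \code{auc} (macro average), \code{perClass}, and
#'   \code{skipped}.
#' @export
threeClassAuc <- function(weights, ref) {
  R <- .adjacency(ref)
  W <- .adjacency(weights)
  off <- .offDiagMask(nrow(W))
  w <- W[off]; r <- sign(R[off])
  classes <- list(activation = list(y = r == 1, s = w),
                  none = list(y = r == 0, s = -abs(w)),
                  inhibition = list(y = r == -1, s = -w))
  per <- c(activation = NA_real_, none = NA_real_, inhibition = NA_real_)
  for (cl in names(classes)) {
    y <- classes[[cl]]$y
    if (!any(y) || all(y)) next
    per[cl] <- .binaryAuc(classes[[cl]]$s, y)
  }
  skipped <- names(per)[is.na(per)]
  list(auc = mean(per, na.rm = TRUE), perClass = per, skipped = skipped)
}

.binaryAuc <- function(s, y) {
  # Mann-Whitney with ties counted half
  r <- rank(s)
  nPos <- sum(y); nNeg <- sum(!y)
  (sum(r[y]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Permutation baseline for network evaluation
#'
#' Random guessing with the reference's edge count: each permutation
#' relocates the reference's edges uniformly among the off-diagonal
#' slots and scores the resulting guess against the reference. When an
#' observed value is supplied, the empirical p-value
#' \code{(1 + #\{null >= observed\}) / (nPerm + 1)} is returned.
#'
#' @param ref reference network or adjacency matrix.
#' @param metric "sn", "sp", "pr", "ac", "auc_roc" or "auc_pr".
#' @param observed optional observed metric value.
#' @param nPerm number of permutations.
#' @param seed RNG seed (the null sample is a pure function of it).
#' @return list with \code{null} (numeric draws), \code{mean}, and
#'   \code{p} (NA without an observed value).
#' @export
permutationBaseline <- function(ref, metric = "auc_roc", observed = NULL,
                                nPerm = 100L, seed = 1L) {
  R <- .adjacency(ref)
  n <- nrow(R)
  slots <- which(.offDiagMask(n))
  nE <- sum(R[slots] != 0)
  set.seed(as.integer(seed))
  draws <- vapply(seq_len(nPerm), function(p) {
    G <- matrix(0, n, n)
    G[sample(slots, nE)] <- 1
    if (metric %in% c("auc_roc", "auc_pr")) {
      a <- rocPrAuc(G, R)
      if (metric == "auc_roc") a$aucRoc else a$aucPr
    } else {
      er <- confusionMetrics(G, unname(R) != 0, mode = "directed")
      slot(er, c(sn = "sn", sp = "sp", pr = "pr", ac = "ac")[metric])
    }
  }, 0)
  p <- if (is.null(observed)) NA_real_ else
    (1 + sum(draws >= observed)) / (nPerm + 1)
  list(null = draws, mean = mean(draws), p = p)
}

#' Transitive closure of a network
#'
#' Unsigned reachability closure: the result has an edge a -> b
#' whenever the input contains a directed path from a to b. Idempotent.
#'
#' @param net a \code{\linkS4class{SignalingNetwork}} or adjacency
#'   matrix.
#' @return object of the same kind with binary edge weights.
#' @export
transitiveClosure <- function(net) {
  A <- .adjacency(net)
  g <- igraph::graph_from_adjacency_matrix((A != 0) * 1, mode = "directed")
  d <- igraph::distances(g, mode = "out")
  C <- (d < Inf) * 1
  diag(C) <- 0
  dimnames(C) <- dimnames(A)
  if (is(net, "SignalingNetwork"))
    SignalingNetwork(C, bias = net@bias, nodes = net@nodes,
                     sources = net@sources, sinks = net@sinks)
  else C
}
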