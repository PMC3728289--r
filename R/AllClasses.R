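#' @import methods
#' @importFrom stats median mad rnorm runif var setNames quantile sd
#' @importFrom utils read.delim write.table packageVersion
NULL

#' SignalingNetwork: a signed, directed protein interaction graph
#'
#' The central graph object: an ordered set of node labels, a signed
#' weight matrix whose entry \code{weights[j, i]} is the influence of
#' node \code{j} on node \code{i} (positive = activation, negative =
#' inhibition, zero = no edge), a per-node bias giving baseline activity
#' in the absence of regulation, and optional source (receptor-like) and
#' sink (terminal) node sets. Self-loops are forbidden; cycles of length
#' two or more are permitted.
#'
#' @slot nodes character vector of node labels (length n).
#' @slot weights n x n numeric matrix, zero diagonal.
#' @slot bias numeric vector of length n.
#' @slot sources character, subset of \code{nodes}.
#' @slot sinks character, subset of \code{nodes}.
#' @export
setClass("SignalingNetwork",
  representation(nodes = "character", weights = "matrix",
                 bias = "numeric", sources = "character",
                 sinks = "character"))

setValidity("SignalingNetwork", function(object) {
  n <- length(object@nodes)
  msg <- character()
  if (n < 1L) msg <- c(msg, "at least one node required")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node labels")
  if (!all(dim(object@weights) == c(n, n)))
    msg <- c(msg, "weights must be an n x n matrix")
  else if (any(diag(object@weights) != 0))
    msg <- c(msg, "self-loops are forbidden (non-zero diagonal)")
  if (length(object@bias) != n) msg <- c(msg, "bias must have length n")
  if (!all(object@sources %in% object@nodes))
    msg <- c(msg, "sources must be a subset of nodes")
  if (!all(object@sinks %in% object@nodes))
    msg <- c(msg, "sinks must be a subset of nodes")
  if (length(msg)) msg else TRUE
})

#' InferenceConfig: tuning parameters of the inference linear program
#'
#' @slot epsilon margin enforced between the linear input of active and
#'   inactive genes; on data normalized to roughly [0, 1] the default 0.1
#'   is well below the separation of the two measurement Gaussians.
#' @slot lambda non-negative penalty on the constraint-violation slack
#'   variables; 0 makes slack free up to its cap, large values forbid it.
#' @slot slackCapFactor slack upper bound is
#'   \code{slackCapFactor * var(observations)}.
#' @slot parentValueMode "discretized" (parents enter constraints as 0/1
#'   states) or "continuous" (raw observed values).
#' @slot priorEdgeMin magnitude bound imposed on known edges.
#' @slot degreeDelta minimal absolute-weight in/out-degree imposed on
#'   non-source/non-sink nodes when source/sink identities are declared.
#' @slot solverTolerance primal feasibility tolerance.
#' @slot normalizeSlack divide lambda by the number of inactive cells
#'   (the number of constraints that may be violated); FALSE uses raw
#'   \code{lambda * sum(slack)}.
#' @export
setClass("InferenceConfig",
  representation(epsilon = "numeric", lambda = "numeric",
                 slackCapFactor = "numeric", parentValueMode = "character",
                 priorEdgeMin = "numeric", degreeDelta = "numeric",
                 solverTolerance = "numeric", normalizeSlack = "logical"),
  prototype(epsilon = 0.1, lambda = 1, slackCapFactor = 1,
            parentValueMode = "discretized", priorEdgeMin = 1,
            degreeDelta = 0.1, solverTolerance = 1e-7,
            normalizeSlack = TRUE))

setValidity("InferenceConfig", function(object) {
  msg <- character()
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be > 0")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@slackCapFactor <= 0) msg <- c(msg, "slackCapFactor must be > 0")
  if (!object@parentValueMode %in% c("discretized", "continuous"))
    msg <- c(msg, "parentValueMode must be 'discretized' or 'continuous'")
  if (object@priorEdgeMin <= 0) msg <- c(msg, "priorEdgeMin must be > 0")
  if (object@degreeDelta <= 0) msg <- c(msg, "degreeDelta must be > 0")
  if (length(msg)) msg else TRUE
})

#' LPSpec: an assembled linear program
#'
#' Variables are non-negative; absolute values in the objective are
#' linearized by variable splitting (w = w+ - w-, b = b+ - b-). Each
#' constraint row carries a provenance tag and, where it belongs to a
#' single target gene, the gene index, which \code{\link{solveLP}} uses
#' to decompose the program into independent per-gene blocks.
#'
#' @slot nodes node labels of the underlying network.
#' @slot objective named numeric vector of objective coefficients.
#' @slot A constraint matrix (sparse, rows = constraints).
#' @slot dir constraint directions, one of "<=", ">=", "=".
#' @slot rhs right-hand sides.
#' @slot upper per-variable upper bounds (Inf = unbounded); lower bounds
#'   are all zero.
#' @slot varTag one of "w+", "w-", "b+", "b-", "xi" per variable.
#' @slot varGene target-gene index per variable.
#' @slot conTag one of "active", "inactive", "prior_edge", "degree_in",
#'   "degree_out" per constraint.
#' @slot conGene target-gene index per constraint (NA for rows coupling
#'   several genes).
#' @slot nInactive number of slack variables (inactive, non-targeted,
#'   observed cells).
#' @slot refine secondary (tie-break) objective: per variable, the
#'   number of observed cells contradicting it (an activating edge
#'   whose parent is active while the child is inactive, an inhibitory
#'   edge whose parent is active while the child is active, a bias
#'   pushing against an observed state). Among minimum-cost solutions,
#'   \code{\link{solveLP}} minimizes this contradiction-weighted mass,
#'   making the reconstruction deterministic when the L1 optimum is
#'   degenerate.
#' @export
setClass("LPSpec",
  representation(nodes = "character", objective = "numeric",
                 A = "Matrix", dir = "character", rhs = "numeric",
                 upper = "numeric", varTag = "character",
                 varGene = "integer", conTag = "character",
                 conGene = "integer", nInactive = "integer",
                 refine = "numeric"))

setValidity("LPSpec", function(object) {
  msg <- character()
  nv <- length(object@objective)
  if (ncol(object@A) != nv) msg <- c(msg, "A column count != #variables")
  if (nrow(object@A) != length(object@rhs))
    msg <- c(msg, "A row count != #rhs")
  if (length(object@dir) != length(object@rhs))
    msg <- c(msg, "dir length != #rhs")
  if (!all(object@dir %in% c("<=", ">=", "=")))
    msg <- c(msg, "dir entries must be '<=', '>=' or '='")
  if (length(object@upper) != nv) msg <- c(msg, "upper length != #variables")
  if (sum(object@varTag == "xi") != object@nInactive)
    msg <- c(msg, "nInactive != number of xi variables")
  if (length(msg)) msg else TRUE
})

#' InferenceResult: solution of the inference linear program
#'
#' @slot network the inferred \code{SignalingNetwork} (recombined
#'   weights w+ - w- and bias b+ - b-).
#' @slot slacks data.frame with columns gene, experiment, xi (only
#'   non-zero slack values).
#' @slot objectiveValue optimal objective value.
#' @slot status "optimal", "infeasible" or "unbounded".
#' @export
setClass("InferenceResult",
  representation(network = "SignalingNetwork", slacks = "data.frame",
                 objectiveValue = "numeric", status = "character"))

#' CVResult: cross-validated slack-penalty selection
#'
#' @slot bestLambda penalty with minimal mean held-out MSE.
#' @slot mseTable grid x fold matrix of prediction MSE.
#' @slot lambdaGrid the penalty grid.
#' @slot runWeights list of weight matrices, one per fold, fitted at
#'   \code{bestLambda}.
#' @slot foldAssignment integer fold id per held-out-eligible cell
#'   (named "experiment:gene").
#' @slot seed RNG seed that produced the fold assignment.
#' @export
setClass("CVResult",
  representation(bestLambda = "numeric", mseTable = "matrix",
                 lambdaGrid = "numeric", runWeights = "list",
                 foldAssignment = "integer", seed = "integer"))

#' EdgeSummary: robust edge aggregation across inference runs
#'
#' @slot medianWeight elementwise median of run weight matrices.
#' @slot madWeight elementwise unscaled median absolute deviation.
#' @slot keepMask binary; 1 where |median| > MAD.
#' @slot finalWeight medianWeight * keepMask.
#' @export
setClass("EdgeSummary",
  representation(medianWeight = "matrix", madWeight = "matrix",
                 keepMask = "matrix", finalWeight = "matrix"))

#' EvaluationReport: scoring of a predicted network against a reference
#'
#' @slot tp,tn,fp,fn confusion counts over scored ordered node pairs.
#' @slot sp,sn,pr,ac specificity tn/(tn+fp), sensitivity tp/(tp+fn),
#'   precision tp/(tp+fp), accuracy (tp+tn)/total, reported to two
#'   decimals.
#' @slot aucRoc,aucPr areas under the ROC and precision-recall curves
#'   (NA when not computed).
#' @slot pValues named numeric, empirical permutation p-values.
#' @slot mode "directed", "rep" or "unsigned".
#' @export
setClass("EvaluationReport",
  representation(tp = "numeric", tn = "numeric", fp = "numeric",
                 fn = "numeric", sp = "numeric", sn = "numeric",
                 pr = "numeric", ac = "numeric", aucRoc = "numeric",
                 aucPr = "numeric", pValues = "numeric", mode = "character"))

setValidity("EvaluationReport", function(object) {
  tot <- object@tp + object@tn + object@fp + object@fn
  ok <- function(stored, num, den)
    is.na(stored) || den == 0 ||
      abs(stored - roundHalfUp(num / den, 2L)) < 1e-9
  msg <- character()
  if (!ok(object@sp, object@tn, object@tn + object@fp))
    msg <- c(msg, "sp inconsistent with counts")
  if (!ok(object@sn, object@tp, object@tp + object@fn))
    msg <- c(msg, "sn inconsistent with counts")
  if (!ok(object@pr, object@tp, object@tp + object@fp))
    msg <- c(msg, "pr inconsistent with counts")
  if (!ok(object@ac, object@tp + object@tn, tot))
    msg <- c(msg, "ac inconsistent with counts")
  if (length(msg)) msg else TRUE
})

#' GaussianObservationModel: two-component measurement model
#'
#' Continuous observations of an active gene are modeled as
#' N(muActive, sigma^2), of an inactive gene as N(muInactive, sigma^2),
#' with per-gene means and a shared standard deviation.
#'
#' @slot muActive,muInactive per-gene means (named numeric).
#' @slot sigma shared standard deviation, > 0.
#' @export
setClass("GaussianObservationModel",
  representation(muActive = "numeric", muInactive = "numeric",
                 sigma = "numeric"))

setValidity("GaussianObservationModel", function(object) {
  msg <- character()
  if (length(object@muActive) != length(object@muInactive))
    msg <- c(msg, "muActive and muInactive must have equal length")
  if (any(object@muActive <= object@muInactive))
    msg <- c(msg, "muActive must exceed muInactive for every gene")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the knockdown-screen simulator
#'
#' Defaults mirror the simulation protocol used throughout the package's
#' benchmarks: unit-weight edges, source biases drawn from N(0.95, 0.01),
#' measurement model N(0.95, sigma) for active and N(0.245, sigma) for
#' inactive genes on a [0, 1] activity scale, a shared activation
#' threshold of 0.6, and three replicates per experiment.
#'
#' @slot nNodes,nEdges network size; nEdges <= nNodes*(nNodes-1).
#' @slot fracInhibitory fraction of edges given weight -1.
#' @slot nDoubleKnockdowns number of random double-knockdown experiments.
#' @slot nReplicates replicates per experiment.
#' @slot sigma measurement noise s.d.
#' @slot muActive,muInactive measurement means for active/inactive genes.
#' @slot sourceBiasMean,sourceBiasSd bias distribution of source nodes.
#' @slot thetaDefault shared activation threshold.
#' @slot seed RNG seed.
#' @export
setClass("SimulationConfig",
  representation(nNodes = "integer", nEdges = "integer",
                 fracInhibitory = "numeric", nDoubleKnockdowns = "integer",
                 nReplicates = "integer", sigma = "numeric",
                 muActive = "numeric", muInactive = "numeric",
                 sourceBiasMean = "numeric", sourceBiasSd = "numeric",
                 thetaDefault = "numeric", seed = "integer"),
  prototype(nNodes = 10L, nEdges = 13L, fracInhibitory = 0,
            nDoubleKnockdowns = 5L, nReplicates = 3L, sigma = 0.01,
            muActive = 0.95, muInactive = 0.245, sourceBiasMean = 0.95,
            sourceBiasSd = 0.01, thetaDefault = 0.6, seed = 1L))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nNodes < 1L) msg <- c(msg, "nNodes must be >= 1")
  if (object@nEdges > object@nNodes * (object@nNodes - 1L))
    msg <- c(msg, "nEdges exceeds the number of ordered node pairs")
  if (object@fracInhibitory < 0 || object@fracInhibitory > 1)
    msg <- c(msg, "fracInhibitory must be in [0, 1]")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (object@muActive <= object@muInactive)
    msg <- c(msg, "muActive must exceed muInactive")
  if (object@thetaDefault <= 0) msg <- c(msg, "thetaDefault must be > 0")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' PerturbationExperiment: knockdown screen data container
#'
#' A \code{SummarizedExperiment} subclass holding one column per
#' measurement sample (experiment x replicate) and one row per gene.
#' Assays: \code{activity} (continuous measurements, NA = missing),
#' \code{knockdown} (binary; 1 where the column's experiment targets the
#' row's gene) and optionally \code{trueState} (simulator ground truth).
#' \code{colData} carries \code{experiment} and \code{replicate};
#' \code{rowData} carries the per-gene activation threshold \code{theta}.
#'
#' @export
#' @import SummarizedExperiment
setClass("PerturbationExperiment", contains = "SummarizedExperiment")

setValidity("PerturbationExperiment", function(object) {
  msg <- character()
  if (!all(c("activity", "knockdown") %in% assayNames(object)))
    msg <- c(msg, "assays 'activity' and 'knockdown' are required")
  if (!all(c("experiment", "replicate") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain 'experiment' and 'replicate'")
  if (!"theta" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'theta'")
  else if (any(rowData(object)$theta <= 0))
    msg <- c(msg, "thresholds theta must be positive")
  kd <- assay(object, "knockdown")
  if (!all(kd %in% c(0, 1))) msg <- c(msg, "knockdown assay must be binary")
  if (length(msg)) msg else TRUE
})
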