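---
title: "Reconstructing signaling networks from knockdown screens by linear programming"
author: "perturbLP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing signaling networks from knockdown screens by linear programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbLP)
```

## The model

A signaling pathway is represented as a signed, directed graph over
proteins. Protein $i$ carries a binary activity state $x_i \in \{0,1\}$
and a continuous measured activity $d_{ik}$ in perturbation experiment
$k$ (e.g. antibody fluorescence or RPPA intensity). The model assumes a
threshold activation rule: with edge weights $w_{ji}$ (positive =
activation, negative = inhibition), bias $b_i$ (baseline activity, e.g.
receptor stimulation) and a positive per-gene threshold $\theta_i$,

$$ x_i = 1 \iff \sum_{j \ne i} w_{ji}\, x_j + b_i \ge \theta_i. $$

Incoming activations therefore combine *disjunctively*: any
sufficiently strong subset of active parents activates the child. This
is what lets the model distinguish a direct edge $a \to c$ from the
path $a \to b \to c$ — silencing $b$ leaves $c$ active only if the
direct edge exists. Self-loops are forbidden; longer cycles are
allowed. An RNAi knockdown clamps its targets to $x = 0$ and removes
them from regulation; combinatorial knockdowns clamp several genes at
once. The binary experiment-by-gene matrix $Z$ records the targets.

State propagation (`propagateStates`) runs a synchronous fixed-point
iteration started from the baseline state
$x^0_i = [\,b_i \ge \theta_i\ \text{and not targeted}\,]$, with a
budget of $2n$ sweeps. On acyclic graphs this reproduces evaluation in
topological order exactly (the test suite checks this against an
independent topological oracle). On cycles a fixed point may not
exist; a period-2 oscillation is detected and resolved to the
elementwise AND of the two cycle states with `converged = FALSE` —
flagged, never raised, because downstream code treats non-convergence
as data. Whether unstable cycles deserve different handling is
genuinely open; flagging is the conservative choice. Equality at the
threshold counts as active everywhere (one convention, applied
uniformly to discretization and propagation).

## The inference linear program

Observations are discretized per gene, $x_{ik} = [\,d_{ik} \ge
\theta_i\,]$. Every observed, non-targeted cell $(i,k)$ then constrains
the unknown incoming weights of gene $i$:

* active cell: $\sum_j a_{jk} (w^+_{ji} - w^-_{ji}) + b^+_i - b^-_i
  \ge \theta_i + \varepsilon$,
* inactive cell: $\sum_j a_{jk} (w^+_{ji} - w^-_{ji}) + b^+_i - b^-_i
  - \xi_{ik} \le \theta_i - \varepsilon$,

where $a_{jk}$ is the parent's discretized state (0 for genes silenced
in experiment $k$), $\varepsilon > 0$ is a margin separating the two
state classes, and $\xi_{ik} \ge 0$ are slack variables that absorb
noise-driven contradictions. The objective

$$ \min\ \sum |w| + \sum |b| + \frac{\lambda}{N_0} \sum \xi $$

(absolute values linearized by the standard split $w = w^+ - w^-$,
$b = b^+ - b^-$) is the L1/lasso parsimony principle: the sparsest
network consistent with the perturbation responses, with $N_0$ the
number of inactive cells (the constraints that may be violated) and
$\lambda \ge 0$ trading sparsity against slack use. Missing
observations drop their own constraint; a missing *parent* value takes
its worst case — 0 in active constraints (it cannot help) and 1 in
inactive ones (it might hurt). The unnormalized $\lambda \sum \xi$
variant is selectable (`normalizeSlack = FALSE`).

Tunable parameters, defaults chosen for measurements normalized to
roughly $[0,1]$:

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 0.1 | margin between state classes; must be well below the separation of the two measurement means |
| `lambda` | CV-selected | slack penalty |
| `slackCapFactor` | 1 | slack bound multiplier on $\mathrm{Var}(D)$ |
| `priorEdgeMin` | 1 | forced magnitude of known edges |
| `degreeDelta` | 0.1 | minimal degree mass under source/sink constraints |
| `solverTolerance` | 1e-7 | primal feasibility tolerance |

Three numerical choices deserve explanation.

**Slack cap.** Slack is bounded by
$\xi \le \max(c \cdot \mathrm{Var}(D),\ 2\varepsilon)$ with $c$ =
`slackCapFactor`: the variance term scales the allowance with data
noisiness, and the $2\varepsilon$ floor is the feasibility bound — a
direct contradiction (the same gene observed active and inactive under
identical parent states) needs slack $2\varepsilon$, and with the floor
the program always admits the feasible point $w = 0$,
$b = \theta + \varepsilon$, $\xi = 2\varepsilon$. Without the floor,
contradiction-rich inputs (notably under the worst-case substitutions
of heavily missing data) become infeasible and no network is returned
at all.

**Degeneracy and the contradiction tie-break.** The L1 optimum is not
always unique. On a noise-free chain $a \to b \to c$ observed under
single knockdowns, the cost of explaining $c$ can be spread between
$w_{bc}$ and a spurious shortcut $w_{ac}$ at identical total cost, so
the solution the simplex reports would depend on arbitrary pivoting.
`solveLP` therefore solves lexicographically: after finding the
minimum cost, it minimizes — at fixed cost — the weight placed on
*data-contradicted* variables: an activating edge whose parent is
observed active while the child is inactive, an inhibitory edge whose
parent is active while the child is active, and bias pushing against
an observed state. This secondary criterion is part of the method: it
prefers, among equally parsimonious networks, the one whose edges are
consistent with the observed co-response patterns, and it makes
reconstruction deterministic (the chain above is recovered exactly,
with zero off-chain mass).

**Decomposition.** Every activity constraint touches only the incoming
weights of one gene, so without out-degree (sink) constraints the
program separates into $n$ independent blocks solved separately — the
reason inference scales to dozens of nodes in seconds. The solver is a
dense two-phase primal simplex (Dantzig pricing with a Bland
fallback), cross-checked in the test suite against two independent
simplex implementations and a brute-force grid oracle on small
instances; primal feasibility of every reported optimum is asserted
programmatically.

Prior knowledge enters as constraints: a known activation $j \to i$
forces $w_{ji} \ge$ `priorEdgeMin` (inhibitions symmetrically), and
declared receptor (source) and terminal (sink) identities force every
non-source to carry incoming weight mass and every non-sink outgoing
mass of at least `degreeDelta`. Out-degree rows couple gene blocks, so
inference with sink constraints solves the joint program.

## Selecting the slack penalty

`selectLambdaCV` scores each $\lambda$ on a grid by held-out
prediction: held-out cells are marked missing, the LP is refitted,
states are propagated from the fitted network, and the held-out
observation is predicted as the per-gene mean of the training cells in
the predicted state (genes observed in only one state fall back to the
global mean of the other state; with no information at all, to
$\theta \pm \varepsilon$). The $\lambda$ with minimal mean squared
error wins; exact ties break to the smallest $\lambda$ (the weaker
regularization statement). The held-out unit is a single
(experiment, gene) cell. Two schemes are provided: `"loo_cells"`
(single cells held out one at a time, default 100 random cells — used
for small screens) and `"kfold"` (state-stratified k-fold over cells —
used for larger screens where leave-one-out would be slow). Fold
assignment is a pure function of the seed. The default grid is
$\{0, 0.01, 0.1, 0.5, 1, 5, 10, 50\}$.

Edge weights learned across CV runs are aggregated per edge by the
median, and an edge is kept only when $|\text{median}|$ exceeds the
(unscaled) median absolute deviation across runs — only robustly
learned edges survive. For replicate-rich data, `bootstrapAggregate`
resamples replicates with replacement per cell, runs the whole CV per
bootstrap sample, and medians across samples.

## The simulator

`simulateScreen` emulates an RNAi knockdown screen: a random sparse
topology (uniform distinct ordered pairs, no self-loops; weight $+1$,
a configurable fraction flipped to $-1$; in-degree-zero nodes are the
sources), a design of single knockdowns of every gene plus
`nDoubleKnockdowns` random doubles and one unperturbed control, and
per replicate and experiment: source biases drawn from
$N(0.95, 0.01)$ (redrawn each replicate and experiment; targeted
sources excluded), deterministic propagation to the fixed point, and
measurements $N(0.95, \sigma)$ for active and $N(0.245, \sigma)$ for
inactive genes with a shared activation threshold $\theta = 0.6$. The
two means sit on the $[0,1]$ activity scale consistent with the 0/1
worst-case substitutions; all are configurable. Replicates are
summarized by the arithmetic mean before inference (median
selectable). Connectivity and acyclicity are not enforced; the
benchmarks use about 1.3 edges per node, the density typical of
curated pathway extracts.

What the simulator does *not* emulate: per-gene measurement scales and
thresholds (real screens need per-gene $\theta_i$, e.g. the median of
the measured conditions or a mock control), correlated replicate
noise, partial knockdown efficiency, and time-resolved dynamics.
Passing benchmarks therefore demonstrate correct recovery under the
stated generative model, not performance on any particular biological
data set.

One consequence of these conditions is worth stating plainly: with
three replicates averaged, the effective noise at $\sigma = 0.2$ is
$0.2/\sqrt{3} \approx 0.115$ against a smallest discretization margin
of $0.355$, so state flips are $\approx 3$-standard-deviation events
and the noise sweep shows a nearly flat accuracy profile. The
monotonicity check in the acceptance suite pairs noise levels by
common random numbers (identical topologies and standardized draws
across levels) precisely so that the comparison reflects noise alone
rather than network sampling variability.

## Evaluation protocol

`confusionMetrics` scores ordered off-diagonal node pairs (directed
mode), unordered pairs (unsigned mode, for undirected references such
as protein-interaction databases), or a relaxed mode crediting
reversed edges and predictions explained by a directed reference path
(and, symmetrically, counting a reference edge as found when a
predicted edge or path matches it). Specificity, sensitivity,
precision and accuracy are reported to two decimals, rounding half
away from zero — the convention that reproduces published tables
(e.g. $80/128 = 0.625 \to 0.63$). `rocPrAuc` sweeps $|w|$ thresholds
with ties included simultaneously; the PR area uses step-wise average
precision by default because trapezoidal PR interpolation is biased
(trapezoid selectable). `threeClassAuc` handles signed references as a
macro-averaged one-vs-rest area over activation / no-edge /
inhibition, scoring the no-edge class by $-|w|$; this stand-in is
calibrated (chance level 0.5). `permutationBaseline` implements
random guessing with the reference's edge count, relocating edges
uniformly among off-diagonal slots, with the add-one empirical
p-value $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}}+1)$.
`transitiveClosure` provides the reachability closure used to compare
against effects-propagation-style equivalence classes.

## Benchmark problem sizes

The packaged study protocols are scaled to run on one CPU in minutes,
and state their conditions explicitly:

* `benchmarkNetworkSizes`: networks of 16, 24, 32, 44 and 52 nodes,
  $\approx 1.3$ edges/node, 5 doubles, $\sigma = 0.01$, ten-fold CV
  over the reduced grid $\{0, 1, 10\}$, median aggregation.
* `noiseSweep` / `missingDataSweep`: the ten canonical ten-node
  topologies (edge counts 5, 7, 7, 7, 7, 7, 8, 10, 12, 13),
  leave-one-cell-out CV with 40 holdouts over
  $\{0, 0.1, 1, 10\}$; the missing-data sweep hides 10-50% of genes
  completely and keeps $\sigma = 0.01$ so the missingness effect is
  isolated from noise.
* `priorKnowledgeSweep`: same topologies, 0-100% of true edges
  disclosed, fixed $\lambda = 1$.

```{r quick-example, eval = FALSE}
sim <- simulateScreen(simulationConfig(nNodes = 10, nEdges = 13, seed = 3))
cv  <- selectLambdaCV(sim$data, grid = c(0, 0.1, 1, 10),
                      scheme = "loo_cells", nHoldouts = 40, seed = 1)
es  <- summarizeEdges(cv)
rocPrAuc(abs(es@medianWeight), edgeWeights(sim$network) != 0)$aucRoc
```

## Known limitations

* The threshold model is deterministic; stochastic or ODE dynamics and
  time-course data are out of scope.
* LOO-unidentifiable designs exist: if a single experiment is the only
  one separating a direct edge from a shortcut, holding out its cell
  makes the held-out prediction arbitrary among cost-ties. Redundant
  (duplicated) designs restore identifiability.
* The relaxed (REP) scoring rule's false-negative bookkeeping is one
  of several defensible conventions; the one implemented is symmetric
  (a reference edge is found if any predicted edge or path credits
  it) and documented above.
* Networks whose nodes all have incoming edges receive no source bias
  in the simulator and produce all-inactive data from which nothing
  can be learned; the random generator makes this rare but does not
  exclude it.
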