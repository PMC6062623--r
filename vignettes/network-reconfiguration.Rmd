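---
title: "Dynamic network reconfiguration from ROI time series: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic network reconfiguration from ROI time series: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netreconfig)
```

## The scientific problem

Task fMRI studies of memory encoding ask whether the brain's functional
network moves between qualitatively different topological states as task
demands change: a *globally integrated* state — low modularity, short path
lengths, hub regions (notably the hippocampus) wiring across modules — when
information from many systems must be combined, and a *modular, locally
efficient* state — high modularity, hubs retreating into their own
neighbourhood — once a representation has been formed. `netreconfig`
implements the full analysis chain for this question, from ROI time series
to condition contrasts, together with a synthetic generator that plants the
two states with known ground truth so that every stage can be validated
without access to subject data.

The pipeline has six stages:

1. **Temporal preparation** — discrete-cosine high-pass filtering and
   CompCor-style component regression.
2. **Condition binning** — task blocks are grouped by a behavioural rating
   (confidence or vividness, 1–4).
3. **Condition connectivity** — one Fisher-z correlation matrix per
   condition, estimated with HRF-derived per-volume weights.
4. **Graph construction and metrics** — proportional density thresholding
   and binary-graph metrics.
5. **Density sweep contrasts** — paired t-tests per density plus a pooled
   summary statistic.
6. **gPPI** — ROI-level seed-by-condition interaction models.

## Models and estimators

### Condition connectivity

Each condition's blocks define a boxcar that is convolved with the
canonical double-gamma HRF (peak delay 6 s, undershoot delay 16 s, unit
dispersions, 6:1 peak:undershoot ratio, 32 s support), truncated to the run
and rectified at zero. The resulting nonnegative per-volume weights $w_t$
enter a weighted Pearson estimator: weighted means and covariances over
volumes, correlations clipped at $|r| \le 1 - 10^{-6}$ (the Fisher
transform $z = \operatorname{atanh}(r)$ is unbounded at $|r| = 1$), then
Fisher-transformed. Two exact reductions pin the estimator down: uniform
weights reproduce the ordinary Pearson correlation, and binary weights
reproduce the Pearson correlation of the selected volumes. A `"concat"`
mode (binary block masks) is provided because weighting schemes differ
between toolboxes; the mode used is recorded on every matrix.

### Graphs and metrics

A density (cost) threshold $k$ retains the $\mathrm{round}(k\,N(N-1)/2)$
largest off-diagonal $z$ values as unit edges. Signed ranking is the
default (the "strongest connections" convention); an absolute-value mode
ships as an option since either reading is found in practice. Ties are
broken by lexicographic (row, column) order so thresholding is a pure
function of the matrix.

On the binary graph $A$ with degrees $k_i$ and $m$ edges:

* **Modularity.** $B_{ij} = A_{ij} - k_i k_j / 2m$;
  $Q = \tfrac{1}{2m}\sum_{ij} B_{ij}\,\delta(c_i, c_j)$. Communities come
  from Newman's leading-eigenvector method: split on the sign pattern of
  the top eigenvector of $B$, recurse with the generalised matrix
  $B^{(g)}_{ij} = B_{ij} - \delta_{ij}\sum_{k \in g} B_{ik}$, stop when the
  leading eigenvalue or the split's $\Delta Q$ is not positive (tolerance
  $10^{-12}$). A Kernighan–Lin style node-swap refinement after each split
  is on by default (it can only improve the split it refines, though the
  greedy recursion as a whole is still a heuristic). The reported $Q$ is
  always re-evaluated from the final partition with the direct formula.
* **Global efficiency** is the mean of $1/d_{ij}$ over ordered distinct
  pairs with $1/\infty := 0$, i.e. the Latora–Marchiori form, which is
  well-defined on disconnected graphs (the verbal "inverse characteristic
  path length" description degenerates there).
* **Betweenness** $b_i = \frac{1}{(n-1)(n-2)} \sum_{h \ne j \ne i}
  \rho_{hj}(i)/\rho_{hj}$ over ordered pairs, from exact BFS path counts.
* **Flow coefficient** $\mathrm{FC}_i = p_0 / p_p$ with $p_p = d_i(d_i-1)$
  ordered neighbour pairs and $p_0$ the pairs *not* directly connected —
  the pairs whose length-two path actually flows through $i$. Counting all
  length-two paths instead would make the ratio identically 1 on a binary
  graph. Global flow is the unweighted node mean.
* **Participation** $y_i = 1 - \sum_m (k_i(m)/k_i)^2$, against the spectral
  partition of the *same* graph (partitions are re-estimated per
  subject, condition and density; no group partition is imposed).
* **Local efficiency** of $i$ is the global efficiency of the subgraph
  induced by the neighbours of $i$ ($i$ removed), geodesics confined to
  that subgraph.

Degenerate conventions, fixed everywhere: degree-0/1 nodes score 0 on
flow, participation and local efficiency; disconnected pairs contribute 0
to efficiency and betweenness.

### Sweep contrasts

Metrics are computed over the grid $k \in \{0.10, 0.15, 0.20, 0.25\}$ and
compared between conditions with classical paired t-tests at each density.
The pooled *summary* statistic collapses across the grid by treating the
subject-by-density observations as exchangeable pairs, so 14 subjects and
4 densities give $t(55)$. Densities from one matrix are of course not
independent, so the summary df is optimistic; it is retained deliberately
because it is the convention this analysis style reports, and the
per-density tests are always available alongside. No multiplicity
correction is applied across the grid, again by convention. Zero-variance
differences yield a flagged degenerate row rather than an error. For
bilateral hub nodes, `pool_node_scopes()` averages the two nodes per
subject before contrasting (scope `node:hub_mean`), the usual treatment
for paired ROIs.

### gPPI

The ROI-level design per subject contains an intercept, one HRF-convolved
psychological regressor per condition, the standardised seed series, and
one interaction column per condition formed as the element-wise product of
the standardised seed and that condition's psychological regressor — a
signal-level product, without hemodynamic deconvolution (the deconvolution
variant estimates the interaction at the neural level; at ROI resolution
and TR = 2 s the signal-level product is the common pragmatic choice). No
orthogonalisation is applied to the PPI columns: the full-model OLS
apportions shared variance. Per-node condition-difference contrasts are
tested across subjects with a one-sample t plus Benjamini–Hochberg FDR, or
with sign-flip permutation ($\ge 1000$ seeded flips); cluster-extent
correction is not meaningful for 60–335 ROIs and is not offered.

## The synthetic generator

`simulate_cohort()` emulates the study conditions end to end. Each subject
is a 300-volume run at TR = 2 s over 60 nodes in 4 equal modules with 2
hub nodes (the hippocampus-like seeds; 335 nodes are available by
configuration, but the default scale runs the full sweep in seconds while
preserving all structural features). Twenty-four 15-s blocks separated by
10-s rest cycle deterministically through ratings 2, 4, 1, 2, 4, 3, so
ratings invert exactly to conditions (2 = `low`, 4 = `high`; ratings 1 and
3 are distractor blocks mapped to a neutral state and dropped by the
default bin rule, mirroring the exclusion of "guessing" trials).

In-block volumes are drawn from a zero-mean Gaussian with the block
condition's covariance; rest volumes are uncorrelated. Covariance switches
block-wise and is not HRF-smoothed, keeping the planted ground truth
exact — the HRF enters only through the condition weights downstream. Each
`state_spec` sets within/between-module correlations and the hub blend:
the hub's correlation is `hub_local`, split `(1 - hub_cross)` to its own
module and `hub_cross` to foreign modules. If the assembled matrix is not
positive semidefinite, the smallest uniform ridge $\lambda \le 0.1$
(bisection) is added and the diagonal renormalised; an infeasible spec is
rejected outright. Slow drifts (two cosines and a standardised random
walk, mixed into every node with random loadings) are emitted as
`noise_sources` for the CompCor stage, and white noise of sd 0.5 is added
on top of the unit-variance signals — a signal-to-noise ratio in the range
typical of task fMRI ROI averages.

The two planted states are
`low` (integrated): $\rho_{within} = 0.35$, $\rho_{between} = 0.20$,
`hub_cross` = 0.85, `hub_local` = 0.50; and
`high` (modular): $\rho_{within} = 0.45$, $\rho_{between} = 0.05$,
`hub_cross` = 0.05, `hub_local` = 0.75. The within/between levels place
the two states on either side of the integration axis; the modular state's
`hub_local` is set above its $\rho_{within}$ so the hub's own-module edges
survive proportional thresholding even at $k = 0.10$ — otherwise the hub
disconnects at low densities and its neighbourhood metrics lose power.
These separations are calibrated so that a 14-subject cohort separates the
states decisively at the summary contrast; they are a validation
instrument, not an estimate of empirical effect sizes, which this class of
experiment does not report in recoverable form.

What the generator does *not* emulate: head motion, physiological cycles,
spatial smoothness and voxel-level structure, hemodynamic variability
across regions, and non-Gaussian signal features. Passing the recovery
tests therefore shows the *pipeline* is correct and powered under the
planted model, not that any particular empirical dataset would behave this
way.

For gPPI validation the background states must be condition-*independent*
(`uniform_states()`): under the two-state defaults every node's seed
coupling genuinely differs between conditions, so there are no null nodes
to measure a false-positive rate on. A planted coupling
(`inject_ppi_effect()`, amplitude 0.4 signal units on 3 of 60 nodes) is
then the only true effect.

## Numerical choices

* High-pass filtering regresses out a DCT basis (periods above the
  cutoff, default 90 s; 60 s is the usual choice for shorter simulation
  phases) rather than applying a recursive filter: it is the standard fMRI
  drift model, exactly idempotent, and a fixed linear projection. The
  cutoff must exceed $2\,\mathrm{TR}$ and must leave at least half the
  spectrum untouched.
* CompCor components are PCs of the *column-standardised* noise sources
  (scaling between noise channels is arbitrary, and standardisation stops
  one channel dominating); 3 components are removed by default, matching
  the generator's three noise sources (configurable; 5 is a common choice
  on real tissue signals).
* Correlation clipping at $1 - 10^{-6}$; PSD ridge bounded at 0.1;
  spectral stopping tolerances at $10^{-12}$; all TSV writers emit 17
  significant digits so round trips agree to better than $10^{-12}$.
* All randomness flows from one master seed through
  `derive_seeds()`; identical configuration and seed give byte-identical
  outputs.

## Problem sizes used in validation

The shipped validation uses 60-node cohorts of 14 subjects over the
4-density grid (a full cohort sweep takes roughly two seconds), 200
random graphs of up to 12 nodes checked against brute-force enumeration
oracles, exhaustive-partition comparisons on graphs of up to 8 nodes
(4140 partitions each), 100 stochastic-block recovery draws at $N = 40$,
and 20-cohort replicate sets for the directional pattern and gPPI
operating characteristics.

## Known limitations

* The pooled summary df treats densities as independent observations;
  interpret the summary t as a convention-following index, not a
  calibrated test.
* Leading-eigenvector recursion with local refinement is a heuristic;
  on small graphs it sits within 0.05 of the exhaustive optimum in our
  checks, but global optimality is not guaranteed, and refinement of one
  split can occasionally change later splits for the worse.
* Participation coefficients depend on the per-graph estimated partition;
  label noise in the partition propagates into $y_i$.
* The weighted-correlation estimator assumes the HRF-derived weights are
  meaningful sampling weights; no autocorrelation correction (prewhitening)
  is applied.
* gPPI here is ROI-level; voxel-level cluster inference and anatomical
  labelling are out of scope.
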