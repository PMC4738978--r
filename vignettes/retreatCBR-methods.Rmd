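---
title: "Methods: the retreatCBR prediction pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the retreatCBR prediction pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A patient whose endodontic (root-canal) retreatment is being considered
presents as a vector of categorical clinical variables — habits, medical
history, tooth anatomy, treatment technique, post-treatment findings.
The binary outcome is failure of the retreatment within five years
(radiographic lesion plus clinical signs). `retreatCBR` treats the
historical case table as a CBR case memory and runs the classic
retrieve / reuse / revise / retain cycle on it.

The reuse stage is the modelling core. Two discrete Bayesian networks
are learned on the retrieved (retreatment-only) memory:

* **Score-based tabu search.** The node-quality function is the K2-style
  Bayesian–Dirichlet log marginal likelihood with a uniform prior. It is
  decomposable, so single-edge moves (add / delete / reverse) re-score at
  most two nodes. The tabu list forbids undoing the most recent moves
  unless the undo would beat the best structure found (aspiration); the
  search stops after a fixed number of consecutive non-improving moves
  and returns the best structure visited, which by construction never
  scores below the empty graph. The literature offers several
  node-quality functions for this family of searches; we chose the K2
  form because it is closed-form testable (a four-case binary node with
  counts (2,2) must score exactly `log(1/30)`) and standard for
  categorical data.

* **Conditional-independence (constraint-based) search.** Starting from
  the complete undirected graph, an edge is deleted whenever some
  conditioning set makes the pair independent. The test choice follows
  the expected-count rule: Pearson chi-square when at least 80 % of
  expected cell counts exceed 5, otherwise an exact-style branch —
  Fisher's exact test unconditionally, or a seeded Monte-Carlo test of
  the summed per-stratum chi-square statistic under fixed-margins
  sampling when a conditioning set is present (per-stratum statistics
  and degrees of freedom are summed in the chi-square branch).
  Orientation is v-structure detection followed by Meek-style
  propagation; every tie breaks lexicographically so the result is
  deterministic. Conflicting v-structures can imply a directed cycle, in
  which case the final DAG is assembled edge-by-edge in deterministic
  order, reversing or dropping an edge that would close a cycle.

Each network's conditional probability tables are Laplace-smoothed
frequencies, and the posterior of the outcome given a fully observed
case is computed exactly from the outcome's Markov blanket (this equals
full-joint enumeration; the test suite checks the identity to 1e-10).

### The false-negative-averse mixture

With `x_i` the vector of component posteriors on case `i` and
`y_i ∈ {0, 1}` the observed outcome (1 = failure, the clinically costly
class), the component weights minimise

$$ f(\alpha) = \sum_i (\alpha \cdot x_i - y_i)^2
             + k\,(\alpha \cdot x_i - y_i)^2\, y_i,
   \qquad \textstyle\sum_j \alpha_j = 1 . $$

Writing `w_i = 1 + k y_i`, the Lagrange stationarity conditions are the
linear system `2 Σ_i w_i x_i x_iᵀ α − λ 1 = 2 Σ_i w_i y_i x_i` with
`1ᵀα = 1`, solved directly; a singular system (duplicated or affinely
dependent components) is resolved by the minimum-norm solution, which
reduces to equal weights for identical components. Weights are *not*
clamped to [0, 1]: only the sum-to-one constraint is part of the
optimisation, and negative weights are legal and logged.

Two terminological notes, resolved here as package policy. First, `y = 1`
codes the outcome whose missed prediction must be avoided (failure of
retreatment), and `k` multiplies the `y = 1` residual exactly as the
objective above states, although such cost-weighting schemes are
sometimes described from the false-positive side; the coding is exposed
as configuration (`targetPositive`) with this default. Second, a "Local
vs Global" distinction between search variants appears in parts of the
surrounding literature without definition; this package implements one
tabu variant and one conditional-independence variant.

### Revise and retain

The revise stage screens every input variable against the outcome with
three tests: Yates-corrected chi-square for 2×2 tables (uncorrected for
larger tables, where the correction is undefined), Monte-Carlo
chi-square under fixed-margins (Patefield) sampling with the
`(r+1)/(B+1)` estimator, and Fisher's exact test (exact for 2×2,
Monte-Carlo for r×c). `B = 2000` is the default: the estimator's floor
is then `1/2001 = 0.00049975`, and reported p-values are integer
multiples of `1/2001`. A variable is selected when **any** of the three
p-values falls below the level (default 0.05); an "all" mode is
available for a stricter screen. No multiple-testing correction is
applied — the battery is an interpretability aid, not a confirmatory
analysis. The retain stage appends an expert-verified case and is a pure
function of the memory.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `k` (false-negative weight) | 1 | neutral cost asymmetry; raise to push weights toward components that fit failures |
| decision `threshold` | 0.5 | symmetric reading of the mixture score; the score scale makes 0.5 the natural cut |
| CPT `smoothing` | 1 (Laplace) | keeps every posterior strictly inside (0,1), so the quadratic mixture never sees degenerate 0/1 inputs |
| tabu: list length 10, 100 non-improving moves, ≤ 3 parents | — | unspecified in the source method; ≤ 3 parents keeps every CPT stratum estimable from ~200 cases |
| CI search: `alpha` 0.05, conditioning sets ≤ 1, ≤ 3 parents | — | with ~200 cases and up to 5-category variables, strata defined by two conditioning variables are too sparse for valid contingency tests |
| relevance: `B` 2000, level 0.05, mode "any" | — | B matches the reported p-value granularity (multiples of 1/2001); "any" matches the reported selection rule |

## The synthetic generator

No patient-level dataset is distributed, so the generator builds a
ground-truth Bayesian network over the published variable list (42 input
variables with 2–5 categories plus the binary outcome) and samples cases
ancestrally. Design choices:

* the outcome is a **root node** whose CPT equals the requested
  prevalence (105/205), so the model marginal is exact by construction;
* dependent variables draw 1–2 parents from the outcome and earlier
  dependent variables, with every CPT column at least `effectStrength`
  (default 0.3) away from uniform, giving structure learning honest
  signal; the planted dependent variables are the ones the original
  relevance screen reported, so signal sits in realistic places;
* noise variables are parentless and disconnected from the outcome;
* `Retreatments` is generated constant-positive: the modelled population
  is post-retrieve (every case is a retreatment), and the retrieve stage
  itself is tested separately on memories with mixed flags;
* one variable whose category count the published table lists only as
  "Discrete" (`Sessions`) is given 4 categories, in line with the 3–4
  categories of the other preprocessed variables.

What passing tests on this generator do **not** show: real clinical data
has missingness (rejected at load here), measurement error correlated
across variables, label noise in the five-year follow-up, and
dependencies far weaker than the planted 0.3 effect. Synthetic results
certify the machinery — recovery, calibration, optimisation — not
clinical accuracy.

## Numerical choices and degenerate inputs

* Ties in tabu and CI search break by enumeration / lexicographic order;
  all stochastic stages derive sub-seeds from one master seed, so every
  artifact is a pure function of (inputs, config, seed) and re-runs are
  byte-identical.
* The mixture KKT system falls back to a minimum-norm (pseudo-inverse)
  solution only when direct solving fails; the returned α is
  renormalised to remove numerical drift in the constraint.
* A variable degenerate after pruning (e.g. a constant column such as
  the retreatment flag post-retrieve) yields p = 1 on every relevance
  test, and a CI test degenerate in every stratum counts as independence
  — a constant carries no evidence of dependence.
* Identical 5×2cv records make Dietterich's statistic 0/0; this raises a
  degenerate-statistic error (flagged `degenerate` in the comparison
  matrix), never NaN.
* One-class memories are rejected with a clear error before any AUC is
  attempted; empty query tables produce header-only predictions.

## Evaluation harness

Leave-one-out reports the count of correctly classified held-out cases.
By default the two structures are learned once on the full memory and
the CPTs and mixture weights are honestly refit on each fold: a single
held-out case has negligible influence on the learned DAG at n ≈ 200,
while relearning structures per fold multiplies cost by n
(`looRelearnStructure = TRUE` restores literal per-fold relearning).
5×2 cross-validation uses stratified halves (with 105/205 positives,
unstratified halving risks degenerate folds), shares splits across
methods, and records all 20 AUC evaluations; only the held-out
evaluations feed Dietterich's t statistic
`t = p₁⁽¹⁾ / √((1/5) Σ_i s_i²)` with 5 degrees of freedom. The
Mann–Whitney comparison pools each method's 20 AUC values; in the
comparison matrix the upper triangle holds one-sided Mann–Whitney
p-values and the lower triangle one-sided Dietterich p-values, both
oriented so that a small entry flags the column method as significantly
worse than the row method.

Validation problem sizes, chosen to make each property sharp while the
whole suite stays quick: mixture-solver oracle equivalence on 200 random
instances (2–5 components, 5–50 cases, k ∈ {0, 1, 5}); posterior oracle
on 100 random networks of ≤ 6 nodes; skeleton recovery on 20 planted
6-node networks at n = 5000; relevance-battery calibration on 1000 null
tables at n = 300; 5×2cv size on 500 simulated equal-performance
comparisons; the end-to-end pipeline on the 205-case, 43-variable
fixture.

## Known limitations

* Constraint-based search cannot detect non-faithful dependencies
  (e.g. a pure XOR collider whose parents are marginally independent of
  the child); the tabu component usually covers such cases.
* The thirteen off-the-shelf baseline classifiers of the surrounding
  literature are not re-implemented; the evaluation harness accepts any
  posterior-producing trainer through the same interface.
* With ~200 cases, CI tests beyond one conditioning variable and CPTs
  beyond three parents are statistically unsupported, so deeper
  structures are out of reach by design.
* Absolute accuracy/AUC values on the synthetic fixture reflect the
  planted signal strength and are not comparable to results on clinical
  data.
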