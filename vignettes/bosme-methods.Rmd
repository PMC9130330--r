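---
title: "Bayesian-network over-sampling for cost-sensitive classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian-network over-sampling for cost-sensitive classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bosme)
```

## The problem

In a binary classification task with a rare "positive" class, classifiers
trained to maximize accuracy gravitate toward the majority label. When a
false negative costs much more than a false positive — missing a disease,
a fraud, a death in the ICU — accuracy is the wrong target: the quantity
to minimize is the *expected misclassification cost*

$$\mathrm{EC} = \frac{FN \cdot c_+ + FP \cdot c_-}{N}, \qquad
\gamma = \frac{c_+}{c_-} > 1 .$$

This package implements an *indirect* (data-level) route to
cost-sensitivity: enlarge the training set with synthetic minority
instances until the class distribution reflects the costs, then train any
cost-insensitive classifier on the enlarged data.

## The over-sampler

The generator of synthetic minority rows is a Bayesian network fitted to
the minority subset $S_+$ of the training data, class column excluded:

1. **Structure.** `hill_climb()` performs a steepest-ascent search over
   single-arc additions, removals and reversals, scored by the
   log-likelihood of the data under the maximum-likelihood parameters.
   The score decomposes over node families, so each move rescores only
   the families it changes.
2. **Parameters.** `fit_mle()` estimates, for each categorical node, the
   empirical conditional frequency table given each configuration of its
   categorical parents; for each continuous node, a per-configuration
   linear least-squares model in its continuous parents with MLE
   (divide-by-$n$) variance — the conditional linear Gaussian (CLG)
   family. Categorical nodes never have continuous parents. With all
   features continuous the model reduces to a Gaussian network; with all
   categorical, to discrete CPTs.
3. **Sampling.** `logic_sample()` draws complete rows in topological
   order (roots to leaves), each node from its conditional distribution
   given the already-sampled parent values. By the chain rule the rows
   follow the network's joint distribution.
4. **Binding.** The synthetic rows, labelled with the minority class,
   are appended after the original rows, giving the enlarged set
   $\tilde S$.

`bn_fit()` wraps steps 1–2 and returns a classed model object with
`print`, `summary`, `coef`, `logLik` and `simulate` methods; `bosme()`
wraps all four steps.

### How many rows? The cost-derived target proportion

If the minority class is to represent a proportion $q$ of the enlarged
set, the required count is

$$n = \mathrm{round}\!\left(\frac{qM - m_+}{1 - q}\right),$$

rounded half away from zero ("nearest integer" leaves the half-case
open; half-even would change $n$ by one in edge cases, so the convention
is fixed and documented here). The achieved proportion then deviates
from $q$ by at most $1/(M+n)$.

The choice of $q$ comes from the folk ("translation") theorem of
cost-sensitive learning: multiplying the class prior componentwise by the
misclassification costs and renormalizing,

$$\tilde p_+ = \frac{p_+ c_+}{p_+ c_+ + p_- c_-}, \qquad
\tilde p_- = \frac{p_- c_-}{p_+ c_+ + p_- c_-},$$

makes the accuracy-optimal classifier under $(\tilde p_+, \tilde p_-)$
coincide with the expected-cost-optimal classifier under the original
prior. Setting

$$q = \tilde p_+ = \frac{m_+ \gamma}{m_+ \gamma + m_-}$$

therefore bakes the costs into the data. For integer $\gamma$ the two
formulas compose to the exact identity $n = m_+(\gamma - 1)$, with no
rounding — a useful algebraic self-check that the test suite exercises
over a grid. The decision-rule tie $c_- p_- = c_+ p_+$ is resolved
toward "+" (sensitivity-favoring); strict inequalities leave it
undefined otherwise.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `epsilon` | `1e-6` | minimum strict score gain per hill-climbing move |
| `max_parents` | `Inf` | parent-set cap per node |
| `max_iter` | `500` | move cap (exceeding returns best-so-far with a warning) |
| `sigma_floor` | `1e-6` | absolute floor for fitted Gaussian sd |
| `k` (SMOTE) | `5` | neighbour count |

Because the raw log-likelihood score never penalizes complexity, adding
an arc is weakly beneficial on training data; termination rests entirely
on `epsilon`, and `max_parents` is the guard against dense, overfitted
structures on small minority subsets. The default leaves it unbounded —
the plain score-maximization semantics — and the caveat is deliberate:
users with very small $m_+$ should cap it. The per-node sd floor is
`max(sigma_floor, 1e-3 * sd(node))`, so a constant continuous column
still yields a samplable (near-degenerate) Gaussian.

### Numerical and degenerate-input policy

* Search starts from the empty graph; steepest ascent, not
  first-improvement. Ties between equal-gain moves are broken by move
  type (add, remove, reverse), then parent, then child, in node
  declaration order — the search is fully deterministic.
* A categorical parent configuration unseen in the data has no MLE; its
  CPT row is uniform and flagged, which keeps the sampler total without
  smoothing the observed rows. Rows of held-out data that hit a flagged
  row contribute $\log(1/K)$ to the log-likelihood.
* A continuous family's configuration with fewer than two rows, or a
  singular design, falls back to the pooled fit over all rows (flagged,
  a warning case rather than an error).
* Natural logarithms and MLE (biased) variance throughout, matching the
  likelihood-maximization semantics of the score.
* Synthetic continuous values are *not* clipped to the observed range:
  the learned Gaussian is the model, and clipping would break its
  likelihood semantics.

## The SMOTE baseline

The benchmark over-sampler interpolates between a minority instance and
a random one of its $k$ nearest minority neighbours; one uniform draw
places the synthetic point on the segment, and each categorical feature
is copied at random from the instance or the neighbour. Neighbourhoods
use a Gower-style distance — range-standardized absolute difference for
continuous features, 0/1 mismatch for categorical ones. The distance
convention for categorical features is a documented package choice, not
a reproduction of any particular implementation: mainstream SMOTE
implementations differ here, and no canonical rule exists. The baseline
is intentionally minimal; it exists to give the evaluation harness a
comparator, not to cover the SMOTE-variant literature.

## The evaluation pipeline

`run_cv_experiment()` implements a two-stage protocol:

* **Stage 1.** Repeated $k$-fold cross-validation (defaults $k = 10$,
  10 runs). Within each training fold the over-sampler is applied with
  $q$ derived from the costs and *that fold's* class balance; the
  classifier is fitted on the enlarged fold and scored on the untouched
  validation fold (accuracy and expected cost are both recorded).
  Folds are stratified by default: with a rare minority, an
  unstratified split can strand every minority row in one fold and make
  training-fold over-sampling impossible. `stratified = FALSE` restores
  the plain random split.
* **Stage 2.** For each run, `paired_compare()` tests the two methods'
  per-fold scores: a Shapiro–Wilk test on the differences gates between
  the paired $t$-test (normality tenable, compares means) and the
  Wilcoxon signed-rank test (compares medians; zero differences are
  dropped — the common default of the surrounding software ecosystem,
  noted because Pratt's method changes $p$). Runs significantly
  favouring each side accumulate in `counter_plus` / `counter_minus`,
  summarized by the exact binomial point probability
  $P(B(n, 1/2) = \text{counter}_+)$, $n = \text{counter}_+ +
  \text{counter}_-$ — exact in double precision because both
  $\binom{n}{k}$ and $2^{-n}$ are exactly representable at these sizes.
* **Trend.** Per-cost-ratio signed verdicts sum to a $\beta$-score;
  its trend over the $\gamma$ grid is assessed by the Mann–Kendall test
  (tie-corrected variance, continuity-corrected $z$, $\tau$ reported as
  tau-b) with Sen's slope (median pairwise slope per *grid section*,
  i.e. per $\Delta\gamma$ step, with the rank-based normal-approximation
  95% interval), and by Spearman's rank correlation against the grid
  order with the one-sided $t$-approximation p-value.

Classifiers attach through a minimal adapter contract (`fit` on a
dataset table, `predict` labels). The in-repo reference classifier is a
naive Bayes with Laplace-1 smoothing for categorical likelihoods and
per-class Gaussians (floored sd) for continuous ones; logistic
regression (`stats::glm`), random forest and SVM adapters attach to
their ecosystem packages. All randomness derives from one master seed
through a fixed integer splitting rule, and the per-fold over-sampler
seeds are recorded in the result's seed ledger.

## The synthetic-data generators

Every statistical claim in the test suite runs on data with known ground
truth. `random_ground_truth_bn()` draws a random DAG (expected parents
per node set by `arc_density`), Dirichlet CPT rows
(`dirichlet_alpha = 1`: uniform over the simplex), and uniform CLG
parameters. Generation is *class-conditional*: two networks share a
structure, and the negative-class network's parameters are displaced
from the positive-class network's along a fixed random direction scaled
by the `divergence` knob (a shift on CPT logits and CLG intercepts).
Two networks plus a prior give an exactly enumerable Bayes-optimal and
cost-optimal rule on small discrete problems — which is what lets the
folk-theorem equivalence be tested configuration-by-configuration
rather than by sampling, and makes the Bayes error computable so that
larger divergence demonstrably yields more separable classes.

`make_fixture_suite()` writes three seeded, regenerable benchmark-shaped
fixtures spanning the three feature regimes (all-categorical, 1728 rows
with a 7.75% minority; mixed, 462 rows; all-continuous, 306 rows) with a
JSON manifest and ground-truth parameter dumps. These emulate the
*shapes* of public benchmark suites — row counts, feature counts and
kinds, minority fractions. They do not emulate real data's messiness:
feature dependencies really are a sparse DAG, continuous features really
are conditionally Gaussian, and labels are noise-free draws from the
class-conditional models. Passing tests therefore certify the machinery
(the sampler reproduces its model, recovery sharpens with sample size,
the cost identity holds), not performance claims on any real data set.

## Problem sizes in the shipped tests

The suite favours small, exhaustively checkable instances: three-node
binary networks wherever a joint can be enumerated (25 possible DAGs,
brute-forced as the search oracle), 50,000 forward samples for the
total-variation check (observed TV ≈ 0.005 against a 0.02 bound),
minority sizes 500 vs 5000 for the KL recovery comparison over 10
seeds, and a 400-row, 10%-minority problem for the end-to-end
cross-validation smoke test at $\gamma = 20$. These sizes are the
package's own choices, picked so each check is decisive on the scale at
which its oracle is exact. The learned-model KL computation clamps
learned joint probabilities at $10^{-12}$, since an MLE zero cell in a
small sample would otherwise make the divergence infinite.

## Known limitations

* Pure log-likelihood scoring with unbounded parents can overfit small
  minority subsets; penalized scores (BIC/AIC) and tree-width
  constraints are out of scope.
* No inference engine: the network supports sampling and joint
  evaluation only.
* The Wilcoxon branch relies on R's exact/approximate switching; very
  short score vectors (< 3 folds) are rejected outright.
* The SMOTE baseline is a minimal comparator (one distance convention,
  no variants).
* Multi-class problems are handled only by merging down to binary.
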