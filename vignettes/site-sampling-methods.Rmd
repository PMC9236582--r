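---
title: "Lasso-based site sampling for phylogenetic likelihood approximation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lasso-based site sampling for phylogenetic likelihood approximation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Maximum-likelihood tree search spends almost all of its time evaluating the
phylogenetic likelihood of candidate trees. Under the standard assumption
that sites evolve independently given the tree, the log-likelihood of an
alignment with $m$ sites is a sum of per-site terms,

$$\mathrm{LL}(T) = \sum_{i=1}^{m} \mathrm{LL}_i(T),$$

so evaluation cost grows linearly with alignment length. For phylogenomic
alignments with $10^4$ to $10^5$ sites this linear factor dominates.

The observation this package builds on is that per-site log-likelihoods are
strongly correlated across trees: most columns carry redundant information
about how good a tree is. That makes the problem a variable-selection task.
We express $\mathrm{LL}(T)$ as a linear model over the per-site values,

$$\mathrm{LL}(T) \approx \beta_0 + \sum_{i=1}^m \beta_i\, \mathrm{LL}_i(T),$$

and fit it by least squares with an L1 (Lasso) penalty
$\lambda \sum_i |\beta_i|$ on training data consisting of $\eta$ random
trees and their exact per-site log-likelihoods. Setting every
$\beta_i = 1$ and $\beta_0 = 0$ reproduces the identity exactly; the penalty
drives most coefficients to exactly zero, leaving a set of $\tau \ll m$
sites with positive weights that predict the total. The penalty $\lambda$
is chosen so that a target fraction $\zeta$ of sites (1-10%, default 5%)
survives. During tree search, scoring a tree then costs $\tau$ per-site
evaluations instead of $m$.

Coefficients are constrained to be non-negative because a weighted
likelihood evaluation is only meaningful (and only accepted by weighted
evaluation engines) with positive site weights; since site selection runs on
standardized columns with positive norms, positivity of the standardized
coefficients carries over to the reported weights.

The intercept $\beta_0$ shifts every tree's score equally, so it can be
ignored wherever only the ranking of trees matters (as in hill climbing);
`approximate_log_likelihood(..., use_intercept = FALSE)` makes that
explicit.

## The training pipeline

1. **Random trees.** `random_stepwise_topology()` draws topologies by
   inserting taxa in a uniformly shuffled order onto uniformly chosen edges;
   `draw_branch_lengths()` attaches i.i.d. exponential branch lengths with
   mean 0.1 expected substitutions per site. Training computes exact
   per-site log-likelihoods on these trees with no branch-length or model
   optimization — the approximation must rank arbitrary trees, including
   poor ones, so the training distribution deliberately spans tree space
   broadly rather than concentrating near optima.
2. **Design standardization.** Each column of the $\eta \times m$ design is
   centered and divided by its L2 norm so that selection is scale-free;
   the response is centered and the intercept recovered analytically.
   Zero-variance columns (e.g. invariant sites identical across training
   trees) cannot be standardized and are excluded from selection.
3. **Path fitting.** `fit_positive_lasso_path()` runs cyclic coordinate
   descent with the one-sided soft threshold over a grid of 100 penalties,
   log-spaced from the smallest all-zero penalty
   $\lambda_{\max} = 2\max_i x_i^\top y$ down to $10^{-7}\lambda_{\max}$,
   with warm starts. A grid point is converged when the largest coefficient
   update is below $10^{-4}$ times the largest coefficient.
4. **Selection.** `select_sample()` walks the grid from the largest penalty
   and returns the first solution whose active fraction reaches $\zeta$,
   reporting the achieved fraction rather than truncating the model
   (truncation would break the fitted linear combination). Fractions above
   what the grid minimum attains are not reachable and raise an error.

## Likelihood engine

Per-site likelihoods are computed natively by Felsenstein pruning over
unique site patterns (duplicate columns are collapsed with multiplicity
weights; per-site values are broadcast back to original indices, since the
Lasso selects *sites*, and duplicated sites are exactly the correlated
predictors it collapses). Supported models: WAG, JTT, LG with their
published exchangeabilities, and GTR for DNA; among-site rate variation uses
the discrete gamma model with $k$ equal-probability categories (mean-of-
slice discretization, renormalized so the category mean is exactly 1, which
keeps branch lengths in expected-substitution units). Ambiguity codes and
gaps enter as indicator vectors over their compatible states; per-node
scaling with accumulated log scalers prevents underflow. Transition
probabilities come from the symmetric eigendecomposition of the reversible
rate matrix, which also powers the branch-length optimizer: projecting the
inner and outer partial likelihoods of an edge onto the eigenbasis makes the
single-edge likelihood, and its first two derivatives, a cheap function of
the branch length.

Branch lengths are optimized coordinate-wise (bounds $[10^{-8}, 100]$) with
safeguarded Newton steps in log branch length and a bracketed scalar-search
fallback, sweeping edges in postorder. Within a sweep the partials below
each edge are refreshed as the sweep proceeds while the partials above come
from the start of the sweep; if such a sweep ever fails to improve the exact
log-likelihood, it is replayed with fully refreshed partials, which is a
strict coordinate ascent — so the log-likelihood never decreases across
sweeps. Sweeps stop when a full sweep gains less than 0.01 log units
(default) or after 32 sweeps. The gamma shape $\alpha$ is estimated by
bounded scalar search on $[0.02, 100]$ (log scale, relative tolerance
$10^{-3}$), alternating with branch-length optimization.

Site-specific evolutionary rates are posterior means over the gamma
categories (empirical Bayes, equal priors), computed on a maximum-parsimony
stepwise-addition tree with ML-optimized branch lengths; the standardized
copy subtracts the mean and divides by the sample standard deviation (the
choice of sample vs population denominator is immaterial at the alignment
lengths involved, but it is fixed and documented here).

## Tree search

`greedy_spr_search()` climbs by subtree pruning and regrafting. All SPR
neighbors within a rearrangement radius (default 5; radius 1 is exactly the
NNI neighborhood) are scored lazily — no branch-length optimization, with
the regraft edge split in half, the pruned subtree keeping its branch
length, and the two merged edges summed, so total tree length is conserved.
The first neighbor improving the current score by more than $\epsilon$
(default 0.1 log units) is accepted immediately and the scan restarts
(first-improvement with a deterministic enumeration order). At a stall, the
50 best lazily-scored neighbors are branch-length optimized in score order
and the first that improves by more than $\epsilon$ is accepted; the search
ends when none does. Termination follows because accepted scores increase
by more than $\epsilon$ and the likelihood is bounded above for fixed data.

The two-phase variant (`two_phase_search()`) runs phase 1 entirely under
the Lasso approximation (including its stall-stage optimization, performed
on the sampled sites with their weights) to a local maximum, then restarts:
phase 2 still scans lazily under the approximation but optimizes and accepts
its stall candidates on the full alignment, which is what separates
near-optimal topologies. Because phase 2 accepts moves on two different
scales — approximate for lazy moves, exact for optimized ones — a move
accepted on one scale can lower the score on the other; both acceptance
thresholds are therefore held at their running maxima, keeping each
acceptance sequence strictly increasing and the search provably finite
(without this guard the mixed-scale climb can cycle). Final
log-likelihoods are always reported on the full alignment. Evaluation counters distinguish complete per-site
likelihood passes from one-branch objective evaluations, and full-alignment
from sampled-site work, so the cost of search strategies can be compared.

## Synthetic data and what the tests show

`simulate_alignment()` evolves sequences along a tree under the same models
the engine evaluates: root states from the stationary distribution, a
uniformly drawn gamma category per site, and transitions per edge.
Simulation uses the same *discretized* gamma categories as inference, so
recovery tests for $\alpha$ and site rates measure estimation error alone,
not discretization bias. `make_benchmark()` packages the default study
conditions at desk scale: 15 taxa, $m = 2000$ sites, WAG+G4 with
$\alpha = 0.93$, branch lengths exponential with mean 0.1; training uses
$\eta = 200$ trees and $\zeta = 5\%$, and accuracy is measured on 50
held-out random topologies whose branch lengths are ML-fitted on the full
alignment (test trees are realistic candidates, while training trees are
deliberately random). The search benchmark uses 12 taxa and $m = 4000$
DNA sites under GTR+G ($\eta = 300$), and smaller 4-8 taxon instances for
exhaustive-optimum and recovery checks. These sizes keep the full test
suite within tens of minutes on one CPU while leaving the protocols'
structure intact.

Simulated alignments have no alignment error, no indels (gaps appear only
in hand-built fixtures), no among-lineage composition drift and no
model misspecification, and the taxon counts are far below phylogenomic
practice. Passing tests therefore demonstrate correctness of the
implementation and internal consistency of the method under its own model
assumptions — not performance on empirical phylogenomic data.

## Numerical choices and degenerate inputs

* Likelihood scaling: per-node column scalers with accumulated logs;
  clamped at $10^{-300}$ to avoid log-of-zero on impossible patterns.
* Transition-probability entries are clamped at 0 when eigendecomposition
  roundoff produces values like $-10^{-18}$.
* The Lasso grid maximum is inflated by a factor $1 + 10^{-10}$ so the
  first grid point is all-zero under floating-point arithmetic, as the
  grid construction intends.
* Columns that are constant across training trees are flagged and held out
  of the model rather than divided by a zero norm.
* `select_sample()` reports `zeta_achieved`; requesting a fraction above
  the grid minimum's is an error, not a silent truncation.
* A one-category model makes standardized site rates undefined; the
  functions return flagged zeros instead of dividing by zero.
* On the method's own training designs (fewer trees than sites, strongly
  correlated columns) the Lasso solution is not unique: the active-set size
  can dip transiently along the path and two correct solvers can select
  different representatives of a duplicate block at the same penalty.
  The invariants tested are the ones that are well-posed: the all-zero
  solution at the grid maximum, a monotone penalized objective within the
  coordinate-descent sweeps, the growth trend of the active set, and
  agreement with an independent solver in attained objective value.

## Open design points, resolved

* **Rearrangement distance** counts edges between the pruning point and the
  regraft edge (edges adjacent to the merged edge are at distance 1), the
  radius-style semantics of lazy-SPR implementations; a nodes-vs-edges
  off-by-one against other codebases is possible and documented.
* **Penalty-for-fraction selection** takes the first crossing from the
  large-penalty end; the alternative (smallest penalty meeting $\zeta$)
  would select more shrunken, denser models.
* **Phase-1 stall optimization** runs under the approximation rather than
  being skipped, keeping phase 1 a complete, self-contained search.
* **Training never optimizes** branch lengths or model parameters on the
  training trees; model parameters ($\alpha$, frequencies) are fitted once
  per dataset (per partition where a partition scheme is given) on a
  parsimony starting tree before training.
* **Partitioned training** shares one set of training trees across
  partitions, so the concatenated design is exactly the column
  concatenation of the per-partition designs and the two variants differ
  only in how the Lasso is applied. Branch lengths are shared across
  partitions; per-partition branch scaling is out of scope.
* **Baseline weighting**: the random and fastest-rate baselines inflate
  their unweighted samples by $m/\tau$, the unbiased choice for estimating
  a sum from a subsample.

## Limitations

* The engine targets correctness and mid-scale benchmarks, not production
  scale: no SIMD kernels, no site-repeat caching, and tree generation
  runs in R (only pruning and branch optimization are compiled).
* No invariant-sites category, codon models, or model selection.
* The search implements SPR only (no TBR), single starting tree per call.
* Lasso training cost grows with $\eta \cdot m$; the package does not yet
  subsample patterns during training.
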