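---
title: "Dirichlet-tree multinomial regression with spike-and-slab variable selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dirichlet-tree multinomial regression with spike-and-slab variable selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# The problem

Microbiome profiling yields, per subject, a vector of taxon counts that is
compositional (only relative information, constrained by sequencing depth),
overdispersed relative to a multinomial, and structured by the evolutionary
relations among taxa.  A recurring analytical question is which subject-level
covariates — diet, clinical status, environment — are associated with shifts
in community composition, and where in the taxonomy those shifts act.

`dtmbvs` addresses this with a Dirichlet-tree multinomial (DTM) regression
model equipped with spike-and-slab Bayesian variable selection.  Rather than
penalized point estimates, the package samples the full posterior over models,
so selection uncertainty is quantified rather than suppressed.

# The model

Let a rooted tree with leaves matching the count-matrix columns have branches
(parent-to-child edges) indexed $b = 1, \dots, B$, numbered depth-first from
the root with children in input order.  Leaf counts are decomposed along the
tree: each internal node $v$ sees, per subject $i$, the allocation of its
node total among its $C_v$ children (a child's count is the sum of the leaf
counts under it).  The likelihood factorizes over internal nodes into
Dirichlet-multinomial (DM) kernels,

$$ p(y^{(v)}_i \mid \gamma) \;=\;
   \frac{\Gamma(\sum_c \gamma_{ic})}{\Gamma(\sum_c \gamma_{ic} + N^{(v)}_i)}
   \prod_{c}
   \frac{\Gamma(\gamma_{ic} + y^{(v)}_{ic})}{\Gamma(\gamma_{ic})}, $$

with one concentration per branch following a log-linear covariate link gated
by binary inclusion indicators:

$$ \gamma_{ib} \;=\; \exp\!\Big( \alpha_b + \textstyle\sum_{p=1}^{P}
   \zeta_{bp}\, \beta_{bp}\, x_{ip} \Big). $$

Every branch carries its own intercept $\alpha_b$ and coefficient vector; a
covariate influences composition only where its indicator $\zeta_{bp} = 1$.
The DM kernel needs no reference-category constraint — concentrations are
identifiable without a baseline — so all $C_v$ child branches of a node carry
free parameters.  On a star tree (one internal node, $B = J$) the model is
exactly DM regression on the full count matrix, the recommended fallback for
data without usable tree structure; this equivalence is asserted in the test
suite against an independently coded DM implementation.

Priors: $\alpha_b \sim N(0, \sigma^2_\alpha)$ and, where active,
$\beta_{bp} \sim N(0, \sigma^2_\beta)$ (the slab); inactive coefficients sit
on a point mass at zero (the spike).  For the indicators, either

* a marginalized **Beta-Binomial** prior: a common inclusion probability is
  integrated against $\mathrm{Beta}(a, b)$, giving
  $p(\zeta) = B(a + k,\, b + M - k)/B(a, b)$ for $k$ active out of
  $M = B \times P$.  With $a = b = 1$ every indicator has prior inclusion
  probability $1/2$ and the active count is uniform on $0..M$; or
* a **Markov random field** prior over each branch's indicator vector,
  $\exp\{ d \mathbf{1}^\top \zeta_{b\cdot} + f\, \zeta_{b\cdot}^\top G\,
  \zeta_{b\cdot} \}$, sharing a symmetric 0/1 covariate adjacency $G$ across
  branches.  The quadratic form counts each edge twice (both triangles of the
  symmetric $G$); conventions differ across the MRF literature, so we fix
  this one and use it consistently, tests included.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `a`, `b` | 1, 1 | Beta-Binomial hyperparameters; 1,1 is non-informative |
| `sigma2_alpha` | 10 | intercept prior variance (log-concentration scale) |
| `sigma2_beta` | 10 | slab variance; diffuse on the log-linear scale |
| `d` | −2.2 | MRF sparsity (≈ logit 0.1); more negative = sparser |
| `f` | 0.5 | MRF smoothing; kept small — MRF priors have a known phase transition where large `f` floods the model |
| `iterations`, `burn_in` | 150000, 75000 | sampling effort at application scale; small simulations mix orders of magnitude faster |
| `rw_sd_alpha`, `rw_sd_beta` | 0.5 | random-walk proposal spreads; also the add-proposal spread |
| `swap_prob` | 0.5 | fraction of between-model proposals that are within-branch swaps |
| `moves_per_iter` | `⌈BP/10⌉` | between-model proposals per iteration, scaling with the model grid |

`d` and `f` are fixed user constants, not hyperpriors: the MRF's sensitivity
near its phase transition makes automatic calibration fragile, and a fixed,
conservative default is easier to reason about.

# The sampler

Posterior exploration uses Metropolis-Hastings-within-Gibbs:

1. **Between-model moves** (`moves_per_iter` per iteration).  With
   probability `1 − swap_prob`, a uniform cell of the $B \times P$ grid is
   toggled: an *add* proposes $\beta' \sim N(0, \texttt{rw\_sd\_beta}^2)$
   jointly with $\zeta\!:\!0\!\to\!1$; a *delete* proposes
   $\beta \to 0$.  Otherwise a *swap* picks a branch uniformly and proposes
   exchanging one uniformly chosen active and one inactive entry within it
   (a fresh coefficient for the incoming entry).  If the chosen branch has
   no active (or no inactive) entry, the swap degenerates to an add (or
   delete) within that branch.  Because a toggle can then arise from two
   proposal paths, the acceptance ratio uses the total proposal mass of both
   paths in each direction; this keeps every move exactly reversible, which
   the test suite verifies by comparing model-visit frequencies against
   grid-quadrature posterior probabilities on a small problem, and by
   checking prior marginals with the likelihood disabled.
2. **Within-model moves.**  One random-walk Metropolis update per intercept
   and per active coefficient, with symmetric proposals.

The coefficient attached to add/swap proposals is drawn from the random-walk
scale, *not* the slab, with its density included in the Hastings ratio: a
diffuse slab used as a proposal would push acceptance toward zero.

Every proposal perturbs a single branch's concentration column, so only the
owning node's DM kernel is recomputed; per-node caches of the concentration
row sums and per-child terms make one proposal cost $O(n C_v)$ log-gamma
evaluations.  The chain state is never rebuilt multiplicatively from deltas —
proposed columns are recomputed from the proposed parameters — so no
numerical drift accumulates; a from-scratch likelihood audit at the end of
every run enforces this.  The implementation is vectorized R: at the
package's intended scale (tens of branches, tens to a hundred covariates)
the per-proposal cost is dominated by `lgamma` on length-$n$ vectors, which
R executes at native speed, and profiling showed no need for compiled code.

Optional Robbins-Monro adaptation of the random-walk scales runs during
burn-in only (`tune = TRUE`), targeting 44% acceptance; kernels are frozen
afterwards so the post-burn-in chain targets the exact posterior.

# Inference

The marginal posterior probability of inclusion (MPPI) of a pair $(b, p)$ is
the post-burn-in average of its indicator draws.  Selection is either

* **MPPI ≥ 0.5** (the median-probability model), or
* **Bayesian FDR**: rank pairs by descending MPPI; the expected false
  discovery rate of the top $k$ is the mean of $1 - \mathrm{MPPI}$ over
  them; the largest qualifying prefix sets the cutoff.  Ties at the cutoff
  are all included, matching the ≥ convention of the MPPI rule.  The
  implied cutoff is data-dependent — a given $\alpha$ maps to different
  MPPI thresholds on different posteriors — so thresholds should be
  reported alongside selections, not treated as portable constants.

Selected pairs are reported as network edges between the branch's child
label (a taxon for leaf branches; a stable synthesized `node_k` label for
internal branches, which are real findings, not artifacts to drop) and the
covariate, with an optional restriction to the root-to-leaf paths of named
taxa.  Convergence is assessed on the two traces practitioners inspect —
the active-covariate count and the log-posterior — plus a Geweke z-score
computed with AR-fit spectral variance estimates.  Richer diagnostics are
delegated to external MCMC tooling through the plain-CSV sample export.

# The simulator

`simulate_scenario()` generates data through the exact DTM forward model:
covariates from a mean-zero multivariate normal with exchangeable
correlation (then standardized), a truth with `n_active` uniformly placed
branch-covariate pairs of effect $\pm$`effect`, intercepts uniform on
$(-0.5, 0.5)$, and counts drawn top-down — Dirichlet child proportions at
each node, multinomial allocation of the node total.  Simulator and
likelihood therefore test each other: the test suite checks node-level
moments, exact count conservation, and average likelihood dominance of the
generating truth.

The reference scenario (the defaults) uses 200 subjects, a random 4-leaf
tree ($B = 6$), 10 uncorrelated covariates, 3 active pairs with
$|\beta| = 1$, and 10,000 reads per subject — a typical 16S depth.  At this
signal strength the sampler recovers all true pairs with MPPI near 1 and
null MPPIs near 0 in 20,000 iterations.  What passing such tests shows is
internal consistency under the model's own data-generating process; real
microbiome data add zero inflation, non-linear effects, and tree
misspecification, none of which the simulator emulates (zero-inflated and
negative-binomial variants are out of scope).

Test problem sizes are deliberately modest — recovery runs use 20,000
iterations on $B \times P = 60$ grids, and the exhaustive-posterior check
uses a two-leaf tree with one covariate so that 4-dimensional quadrature is
feasible — chosen as the smallest problems that exercise every code path
with clear statistical margins.

# Numerical choices and degenerate inputs

* All Gamma-function ratios go through `lgamma`; nothing forms
  $\Gamma(\cdot)$ directly, so counts in the thousands are safe.
* A proposal whose concentrations overflow to `Inf` is rejected rather than
  crashing the chain; the from-scratch likelihood evaluator raises an error
  with a standardization hint instead, since at evaluation time the state
  is user-supplied.
* Unary (single-child) internal nodes are collapsed at parse time: they
  contribute probability-one multinomials and non-identifiable parameters.
* A taxon present in the tree but not the counts (or vice versa) is a hard
  error listing the symmetric difference; silent pruning hides data bugs.
* Zero counts need no pseudocounts — the DM kernel handles them; an
  all-zero subject contributes zero log-likelihood at every node.
* Empty-model initialization with
  $\alpha_b = \log(\text{pooled child proportion} + 0.01)$ starts the chain
  at the sparsity assumption; the offset guards branches with no observed
  counts.
* BFDR with no qualifying prefix returns a select-nothing sentinel (`NA`)
  rather than an error, so null data sets flow through pipelines.

# Known limitations

* The MRF prior acts within each branch's covariate vector, sharing `G`
  across branches; covariate relations are graph-encoded, branch relations
  are carried by the tree itself.  Cross-branch MRF coupling is a plausible
  alternative we did not adopt.
* MCMC over a $2^{B \times P}$ model space is inherently expensive; for
  data sets with many taxa and covariates, the star-tree DM fallback (or
  fewer covariates) is the practical route.  Variational approximations are
  out of scope.
* `G` must be supplied (or thresholded from an empirical correlation matrix
  via `correlation_graph`); graphical-model estimation of `G` is not
  included.
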