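---
title: "Measuring taxon influence on Bayesian phylogenies with the SPR excess"
author: "tii package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring taxon influence on Bayesian phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tii)
```

## The question the index answers

Individual taxa can disproportionately reshape a phylogenetic analysis:
a fossil with mostly missing characters, a fast-evolving lineage, or a
taxon with conflicting signal can all move clades that do not contain
them. The taxon influence index (TII) quantifies this by leave-one-out
jackknifing at the level of whole posterior distributions. For a focal
taxon $i$:

1. run the Bayesian analysis on the full matrix, giving a posterior
   sample of topologies $T^*$;
2. run it again with taxon $i$ deleted from the matrix, giving $T'$;
3. prune taxon $i$ *a posteriori* from every tree in $T^*$, so both
   posteriors range over the same leaf set;
4. report the expected tree distance between the two posteriors,

$$\mathrm{TII}(i) \;=\; \mathbb{E}\,[\,d(T^*_i,\,T'_i)\,]
 \;=\; \sum_{T^*}\sum_{T'} w(T^*)\, w(T')\, d(T^*_i, T'_i),$$

where the weights $w$ are posterior probabilities, estimated here as the
sample frequencies of unique topologies in the post-burn-in sample.  A
large value means removing the taxon changes what the data say about the
*remaining* relationships; a rank over all taxa separates stabilising
taxa from disruptive ones.

The package consumes tree samples (newick lists or MrBayes-style NEXUS
`.t` files; translate tables are resolved and burn-in is discarded as a
fraction of the sampled trees).  Running the Bayesian inference itself is
out of scope: `write_jackknife_matrices()` prepares the drop-one NEXUS
matrices, and the readers pick up the resulting tree files.

## The SPR excess

Robinson–Foulds distances saturate quickly and the branch-score distance
conflates topology with branch lengths, so the index uses a distance
designed to measure disagreement *relative to what the trees still share*:

$$d_{\mathrm{SPR\text{-}excess}}(t_1, t_2) \;=\;
  \frac{d_{\mathrm{SPR}}(t_1, t_2)}{|\mathrm{MAST}(t_1, t_2)|},$$

the minimum number of subtree-prune-and-regraft moves separating the two
topologies, divided by the number of taxa in their maximum agreement
subtree.  Identical topologies score 0; a single rearrangement that
destroys most shared structure scores high.

Two hard sub-problems sit underneath, both implemented in compiled code:

* **MAST.** Computed exactly by a rooted agreement-subtree dynamic
  program maximised over every choice of a shared leaf as root. Any
  agreement subtree contains some leaf, so rooting both trees at that
  leaf reduces the unrooted problem to the rooted one; the kernel is
  $O(n)$ rootings of an $O(n^2)$ table. A witness leaf subset is
  returned along with the size.
* **SPR distance.** Exact values come from a bidirectional breadth-first
  search over the SPR graph with canonical-form deduplication
  (bipartition sets encoded as sorted 64-bit masks). Computing SPR
  distance is NP-hard, so the search is governed by a
  `distance_spec()`: exact search is attempted for trees of at most
  `max_leaves` (default 10) leaves, or whenever a greedy upper bound is
  at most `max_distance` (default 3) moves, subject to a `max_states`
  cap on the search's stored states. Outside those limits the greedy
  bound itself is returned, flagged `exact = FALSE`.

The greedy bound deserves a note: it hill-climbs by always taking the
SPR move that most reduces the RF distance to the target (ties broken by
a fixed enumeration order, so no randomness is involved). Hill-climbing
on RF can stall; when it does, the bound is completed constructively
with one move per leaf outside a maximum agreement subtree of the
current pair — each such leaf can be relocated to its target position
with a single SPR move, so `moves_so_far + (n - |MAST|)` is always
attainable.  The bound is therefore deterministic, always terminates and
never undercuts the true distance (a property the test suite checks
against the exact search on every pair of a seeded batch).

One search refinement matters in practice: a breadth-first search that
has completed levels $d_A$ and $d_B$ from the two ends without meeting
has *proven* the distance exceeds $d_A + d_B$; combined with an upper
bound $b$ from the greedy climb, reaching $d_A + d_B = b - 1$ settles
the distance at exactly $b$ without expanding the deepest level.  This
makes exact distances up to 3 essentially free even on larger trees,
which is what the TII pipeline mostly encounters.

## Estimating the index

`tii_exact()` evaluates the full double sum after merging topologies
that become shape-equal when the focal taxon is pruned (the sum is
invariant to that merging, which the tests verify by splitting weights).
Because the number of summands is the product of the two unique-topology
counts, the package also implements the resampling estimator used for
real posteriors: per iteration, `m = min(|T*|, |T'|)` topologies are
drawn *without replacement* from each side, each draw proportional to
the remaining posterior weights (base R's weighted `sample()` implements
exactly this successive-draw scheme), and the double sum is evaluated
over the drawn subsets.  The estimate is the median of `n_iter = 100`
iterations, with quartiles and Tukey-fence outliers recorded
(`flag_outliers()`; quartiles use linear interpolation, R's default
type 7, so estimates are bit-reproducible).

Two choices here were genuinely open:

* **Within-replicate weighting.** The drawn subset's original weights
  are renormalised to 1 before the double sum (default). This makes a
  whole-set draw reproduce `tii_exact()` identically — a sharp, testable
  anchor. The alternative, uniform weights over draws, is available via
  `weighting = "uniform"`.
* **Resampling depth.** `m` defaults to the `min` rule above but can be
  set lower. The median over replicates converges to the exact sum as
  `m` approaches the full set sizes; the acceptance suite measures mean
  absolute deviations of roughly 0.05 → 0.0002 as `m` grows from 5 to 25
  on 12-taxon pseudo-posteriors. At very small depths (`m` of 2–3) the
  replicate distribution is strongly skewed and its *median* is not a
  monotone-improving estimator — deviations can be smaller at `m = 2`
  than at `m = 6`. This is a property of the median under skew, not a
  defect of the sampler; the consistency checks therefore start at
  moderate depths.

Distances inside one TII computation are memoised by unordered
topology-pair key, which only caches a pure function and cannot change
results.

## Ranking and comparing rankings

`taxon_influence()` runs the resampled estimator for every jackknifed
taxon and ranks taxa by median TII (descending; ties broken
lexicographically so output is deterministic). Rankings are compared
with rank-biased overlap,

$$\mathrm{RBO}(p) = (1-p) \sum_{d=1}^{n} p^{\,d-1} A_d + p^{\,n} A_n,$$

where $A_d$ is the proportion of shared taxa between the two top-$d$
prefixes and the terminal term extrapolates beyond depth $n$ (for the
conjoint full lists used here, $A_n = 1$). The persistence $p$ sets how
top-weighted the comparison is; 0.9 (roughly, the first ten ranks carry
most of the weight) is the default, exposed as a parameter because no
single value is canonical. Note that as $p \to 1$ the *extrapolated*
form converges to $A_n = 1$ rather than to the average overlap across
depths, which holds only for the truncated/infinite variants; the
package implements the extrapolated form throughout.

Significance is assessed by permutation against the null of unrelated
rankings: the second ranking's order is permuted uniformly, and the
one-sided p-value uses the add-one rule
$(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(N+1)$, so it can never fall
below $1/(N+1)$ (default $N$ = 9,999). Under a true null the p-values
are stochastically no smaller than uniform, which the acceptance suite
verifies on 500 seeded draws.

`missing_proportion_ranking()` ranks taxa by their share of missing
(`"?"`) characters — the gap/inapplicable code `"-"` is *not* counted as
missing, though `missing_symbols` can widen the set — and
`fit_tii_vs_missing()` regresses median TII on that proportion by
ordinary least squares, reporting $R^2$ and the two-sided slope test.

## What the synthetic generator emulates — and what it does not

All validation runs on seeded pseudo-posteriors, because real inputs
require external MCMC runs. `random_topology()` grows uniformly random
unrooted binary labeled shapes by sequential random edge attachment;
`pseudo_posterior()` scatters `n_unique` distinct topologies within
`max_moves` SPR moves of a center and gives them symmetric-Dirichlet
weights sorted so the center is modal (peaked, like well-converged
posteriors; `flat = TRUE` available for stress tests); random SPR
proposals never regraft a subtree back onto its original edge, so
`max_moves` genuinely bounds displacement.
`planted_influence_suite()` centers each dropped-taxon posterior a known
number of SPR moves away from the pruned base topology, planting a
ground-truth influence ordering.

The validation conditions are fixed as: scenarios of 10–16 taxa with
displacements 0–3 recycled over taxa, posteriors ranging from point
masses to 10 unique topologies within 2 SPR moves of their centers, 20
scenarios per batch, 100 (tests: 20) resampling iterations; resampler
consistency uses 12 taxa and 25 unique topologies per posterior. Across
such batches the mean Spearman correlation between planted displacement
and recovered median TII is about 0.91.

What the generator does **not** emulate: correlated topologies induced
by a likelihood surface (its members are isotropic SPR perturbations),
autocorrelated MCMC sampling, branch-length information (pseudo-
posteriors are purely topological), or any coupling between a taxon's
character data and its influence. Passing the synthetic recovery tests
therefore shows the estimator recovers *planted topological
displacement*; it does not certify behaviour on any particular empirical
matrix.

## Numerical and degenerate-input conventions

* Trees are handled unrooted throughout; degree-2 roots are suppressed
  on read. Polytomies are accepted by the readers and by RF/BSD, but SPR
  and MAST require binary trees and say so.
* Kernels encode leaf sets as 64-bit masks, so tree comparisons support
  at most 64 leaves.
* Weights must be positive and sum to 1 within 1e-9; pruning merges
  shape-equal topologies and conserves total weight exactly.
* Credible sets take the smallest descending-weight prefix reaching the
  level, breaking weight ties by first-seen order.
* Taxon labels are trimmed of outer whitespace and inner whitespace
  becomes `_`; comparisons are exact string equality after that
  normalisation.
* Ranking TSVs carry 15 significant digits so round trips preserve
  order.

## A worked miniature

```{r example}
suite <- planted_influence_suite(10, n_unique = 5, max_moves = 2,
                                 seed = 101)
fit <- taxon_influence(suite$full, suite$dropped, n_iter = 50, seed = 1)
summary(fit)
suite$truth[fit$ranking$taxon]
```

The taxa planted furthest from the base topology surface at the top of
the ranking. `plot(fit)` draws the per-taxon replicate distributions in
rank order, the analogue of the index's usual presentation.

## Limitations

* SPR distances beyond the exact-search limits are upper bounds, and are
  flagged as such; ranks built from bounds can in principle differ from
  ranks built from exact distances, though the two coincide on all
  synthetic batches tested.
* The index compares marginal posteriors of topology only; branch
  lengths enter only if the branch-score metric is selected.
* Leave-k-out influence (clades rather than single taxa) is not
  implemented.
* Posterior weights are plug-in sample frequencies; no smoothing is
  applied for topologies observed once.
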