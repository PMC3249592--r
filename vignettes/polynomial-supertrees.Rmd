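---
title: "Polynomial rooted supertree methods: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polynomial rooted supertree methods: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysup)
ct10k <- count_unrooted_trees(10000)
```

## The problem

A supertree method combines rooted phylogenetic trees with overlapping but
unequal leaf sets into one tree on the union of all leaves. Exhaustive
search is hopeless — on 10,000 leaves there are about
`r sprintf("%.1f x 10^%d", ct10k$mantissa, ct10k$exponent)`
unrooted binary topologies (`count_unrooted_trees()`) — and
matrix-representation methods lean on NP-hard parsimony searches. This
package implements the family of polynomial, graph-guided alternatives for
rooted trees: Build, MinCut (MC), Modified MinCut (MMC), and
Build-with-Distances (BWD), together with the metrics and the simulation
pipeline needed to evaluate them against a known model tree.

All methods share one recursion. For the current taxon set $U$ (initially
all taxa), build a graph on $U$ whose connected components become the
children of the current supertree node, then recurse into each component.
They differ only in how the graph is built and how it is disconnected when
conflicts make it connected.

## Build, MC, and MMC

The **Build graph** joins $x,y \in U$ whenever some input tree, restricted
to its taxa inside $U$, places the last common ancestor of $x$ and $y$
strictly below its root — equivalently, contributes a triplet $xy|z$ with
$z \in U$. For compatible inputs the components recursively spell out a
supertree displaying every input; if the graph is connected on three or
more taxa, the inputs are incompatible and `build_supertree()` says so
(`is_incompatible()`), returning a verdict rather than raising an error.

**MC** keeps going where Build stops. Each edge carries three counters:
`w` (restricted trees supporting the pair), `n_cooccur` (restricted trees
containing both taxa), and `n_contradict = n_cooccur - w`. When the graph
is connected, edges with `n_contradict == 0` — pairs no tree containing
them ever separates — are contracted so they can never be cut. The
contracted graph is then disconnected by removing the union of **all**
global minimum cuts (weights `w`), and the recursion continues.

Deleting the union of all minimum cuts, not an arbitrary one, is what makes
the output invariant under input order and relabeling. We compute that
union exactly at any graph size using the max-flow characterization: an
edge $\{u,v\}$ lies in some global minimum cut if and only if the $u$–$v$
max-flow equals the global minimum cut weight. Both quantities come from
igraph with integer capacities, so the comparison is exact.

Two corner cases are decided here:

* **Contraction collapse.** With many mutually conflicting inputs whose
  pairs are individually uncontradicted, contraction can merge a connected
  component into a single supervertex, leaving nothing to cut. We emit a
  polytomy over the component and warn. This happens regularly in the
  noisy-input regime at deletion ratios of 50% and above, which is why MC
  resolution collapses there while BWD's does not — consistent with the
  known weakness of MC under sparse taxon overlap.
* **MMC.** `modified_mincut_supertree()` protects uncontradicted edges
  with an effectively infinite cut weight so only contradicted edges are
  deletion candidates. Under our bookkeeping every stored uncontradicted
  edge is already contracted, so MC and MMC coincide except through that
  guard; the guarantee that motivates MMC — every input clade contradicted
  by no other input survives — is asserted directly in the test suite.

Ties anywhere (component order, child order) are broken by the
lexicographically smallest leaf label, so outputs are deterministic.

## Build-with-Distances

BWD adds branch-length signal. For leaves $x,y$, $\lambda(x,y)$ is the
distance from $x$ up to $\mathrm{lca}(x,y)$, averaged over input trees
containing both (`lambda_table()`). $\lambda$ is deliberately asymmetric.
It is computed once from the full input trees and reused at every
recursion level: the quantity is defined on input trees, and nothing in
the recursion redefines it on restrictions.

The **BWD graph** extends the Build graph with cross-tree distance edges:
$\{x,y\}$ is added when the pair co-occurs somewhere, some witness $z \in U$
co-occurs with $x$, no single input tree contains all three leaves, and
$\lambda(x,y) < \lambda(x,z)$ strictly. Equality adds nothing.

When the graph is connected, edges are weighted by a support function over
the current clade $U$, built from the **primary evidence**
$p(x,y,z) = \max\{0, \lambda(x,z) - \lambda(x,y)\}$ (zero when either pair
never co-occurs):

$$\mathrm{SAC}(x,y,U) = \sum_{z \in U \setminus \{x,y\}} \min\{p(x,y,z),\, p(y,x,z)\},
\qquad
\mathrm{SAC}_{\max}(x,y,U) = \sum_{z} \max\{p(x,y,z),\, p(y,x,z)\}.$$

The sum ranges over $U \setminus \{x,y\}$ because $p$ requires three
distinct labels. Both functions are symmetric, nonnegative, and satisfy
$\mathrm{SAC} \le \mathrm{SAC}_{\max}$ edgewise; multiplying all input
branch lengths by a constant scales both and leaves the output topology
unchanged.

Disconnection uses the **bisection method**: the smallest edge weight
$\theta$ such that deleting every edge of weight $\le \theta$ disconnects
the graph (`bisection_disconnect()`). Thresholds are compared with exact
equality on stored doubles, candidates scanned in ascending order (the
internal search is a binary search — disconnection is monotone in
$\theta$). If all weights are equal the component falls apart into
singletons, i.e. a polytomy. BWD is always plenary but intentionally does
not guarantee to reproduce a compatible collection's parent tree: distance
signal may overrule topology. It does return any single binary input tree
unchanged, since the recursion never meets a connected conflict there.

## Branch-length reconciliation

BWD assumes branch lengths comparable across inputs. When they are not
(trees estimated from different markers, say), `reconcile_trees()` rescales
each tree by one multiplicative constant $c$ against a reference distance
matrix $D$ (e.g. `alignment_distance_matrix()`, Jukes–Cantor corrected by
default). Three estimators are provided, all over the ratio set
$C = \{D(t,t') / D_T(t,t')\}$ restricted to pairs present in both matrices
with $D_T > 0$:

* `trimmed_mean_constant()` — the $\alpha$-trimmed mean of $C$ (default
  $\alpha = 1/3$), dropping $\lfloor \alpha |C| \rfloor$ values from each
  end; exact scale recovery is guaranteed under up to that many
  corruptions per tail, and symmetric floor-per-side trimming is the
  standard convention.
* `least_squares_constant()` — closed form
  $\sum D \cdot D_T / \sum D_T^2$.
* `minimax_constant()` — minimizes $\max |D - c\,D_T|$; the objective is
  piecewise-linear convex, so the optimum is found exactly among the
  crossing candidates $(D_i + D_j)/(D_{T,i} + D_{T,j})$ (golden-section
  refinement for very large pair sets).

Reconciliation is unnecessary — and skipped by the simulation pipeline —
when all branch lengths come from the same model of sequence evolution.

## Comparison metrics

All metrics operate on rooted trees and, for nonplenary supertrees,
`compare_trees()` first restricts the model tree to the supertree's taxa.

* **Normalized RF**: nontrivial clades (size $\ge 2$, excluding the full
  leaf set) in exactly one tree, divided by the total nontrivial clades of
  both. This realization of "number of internal nodes of both trees" gives
  a range of exactly $[0,1]$ and matches the resolution denominator below.
  Two stars compare at 0 by continuity.
* **Triplet distance**: every 3-subset falls in exactly one of five bins —
  `same`, `diff`, `r1` (resolved only in the model), `r2`, `x` — and
  $d_{TR} = (\mathrm{diff} + r_1 + r_2) / (\mathrm{same} + \mathrm{diff} + r_1 + r_2)$,
  0/0 read as 0. Enumeration is explicit ($O(n^3)$), which is exact and
  fast enough for the problem sizes here. Because restricting a tree to
  two taxa trivially matches any model, small nonplenary trees can score
  deceptively well on RF and $d_{TR}$; the MAST score is the counterweight.
* **MAST**: largest leaf set on which both restrictions agree exactly,
  by dynamic programming over node pairs with exact maximum-weight
  bipartite matching at polytomies (subset-enumeration DP for small
  degree, igraph matching beyond). Normalized by the *unrestricted* model
  leaf count, so excluding taxa costs score.
* **Resolution**: nontrivial clade count over $n - 2$, the count attained
  by a rooted binary tree; 0 for a star, 1 for fully binary.

A zero-length branch is still a bifurcation: triplet extraction treats
topology as authoritative, and branch lengths play no role in any metric.

## The simulation generator

`make_input_trees()` emulates the standard supertree benchmark design:

1. **Model tree**: `yule_tree(n)`, a unit-rate pure-birth process
   (`ape::rphylo`). Branch durations are converted to substitution
   lengths by `deviate_rates()`: each branch gets an independent rate from
   a Normal(1.0, 0.5) truncated to [0.1, 2.0] (rejection sampling, exact),
   times a tree-wide rate. By default the tree-wide rate is set so the
   mean root-to-leaf path is 0.3 substitutions/site — a moderate
   divergence at which reconstruction is noisy but not saturated; only the
   shape of the distribution matters downstream, so this single knob is
   exposed rather than any particular calibration.
2. **Outgroup**: `add_outgroup()` attaches an outgroup below a new root
   with pendant length $1.25 \times d_{\max}$, where $d_{\max}$ is the
   largest pairwise distance of the most distant taxon. If that taxon's
   maximum exceeds the runner-up's by more than 75%, its pendant branch is
   first shortened until the excess is exactly 75% — the most direct
   reading of an ambiguous rule, isolated in one function so it can be
   swapped.
3. **Input trees**: per input tree, an independent uniform deletion of
   $\lfloor \mathrm{ratio} \cdot n \rfloor$ ingroup taxa (the outgroup is
   never deleted), then one of three modes: `clean_restriction` (exact
   restrictions — always compatible), `sequence_nj` (the benchmark mode),
   or `nni_perturb` (restriction plus $k$ random NNI moves, a pure
   topological-noise knob).
4. **Sequences**: `evolve_sequences()` simulates one alignment block per
   input tree under GTR+$\Gamma_4$+I. Defaults are an empirical parameter
   set: frequencies (A, C, G) = (0.3468, 0.3594, 0.0805) with T as the
   complement, exchangeabilities (AC, AG, AT, CG, CT) =
   (0.6750, 27.9597, 1.1677, 0.4547, 20.8760) with GT = 1, gamma shape
   1.1999, invariant proportion 0.4954. Sites are invariant with
   probability $p_{inv}$ (drawn from the stationary frequencies and copied
   to all leaves) or assigned one of four equal-probability discrete-gamma
   categories whose rates are scaled by $1/(1 - p_{inv})$ so the mean rate
   over all sites is 1 and branch lengths read as expected
   substitutions/site. Per-category simulation is delegated to
   `phangorn::simSeq`; the rate matrix construction is exposed as
   `gtr_rate_matrix()` for verification (zero row sums, detailed balance,
   unit mean rate). Block length defaults to 1000 bp up to 144 taxa and
   500 bp beyond.
5. **Reconstruction**: `nj_tree()` is a deterministic neighbor-joining
   stand-in for maximum-likelihood inference — self-contained, orders of
   magnitude faster, and preserving the character of reconstruction noise
   while being somewhat noisier than ML at the same block length.
   Distances are Jukes–Cantor corrected with the p-distance capped just
   below the saturation singularity (under the default scaling, with
   roughly half the sites invariant, observed p-distances stay far from
   the cap). The tree is rooted on the outgroup, the outgroup pruned, and
   negative NJ branch lengths clamped to zero. Taxa are processed in
   sorted label order, so input row order is irrelevant.

All randomness in a replicate flows from the single seed in
`sim_config()`; identical configurations reproduce every tree and sequence
bit-exactly.

What the generator does *not* emulate: model misspecification (inference
assumes the generating process up to the NJ approximation), rate
variation across input datasets (all blocks share one model tree and one
parameter set, so branch lengths are comparable by construction and
reconciliation is skipped), alignment error, and missing data within
sequences. Passing benchmarks here therefore demonstrate correctness of
the algorithms and their relative behavior under taxon-overlap stress, not
performance on real heterogeneous data.

## The benchmark

```{r benchmark}
cfg <- sim_config(n_taxa = 24, deletion_ratio = 0.5, n_input_trees = 6,
                  input_mode = "sequence_nj", seed = 42)
res <- run_benchmark(cfg, methods = c("mc", "bwd_sac"), n_replicates = 3,
                     mast = FALSE)
summarize_benchmark(res)
```

`run_benchmark()` records one row per (replicate, method), flags
incompatible Build runs instead of failing, prunes the outgroup before
comparison, and can append to a CSV so long runs resume by replicate.

Validation in the test suite runs at deliberately modest sizes chosen to
finish in minutes while still separating the methods: exhaustive oracles
up to 6 taxa (compatibility, against all 945 rooted binary topologies),
8 leaves (MAST, against subset brute force), 10 vertices (bisection,
against threshold scans); guarantee and recovery properties on random
trees up to 32 taxa; and the two simulation claims — BWD(SAC) mean
resolution above 0.8 at 75% deletion (96 taxa, 16 input trees) and
BWD(SAC) beating MC on mean triplet distance (48 taxa, 50% deletion, 10
input trees) — each on 20 replicates.

## Known limitations

* MMC here is the edge-classification realization described above, not a
  reimplementation of Page's original graph construction; on inputs where
  the two differ in tie handling, outputs may differ.
* The all-minimum-cuts rule makes MC/MMC order-invariant but can delete
  aggressively when many cuts tie, and contraction collapse produces
  polytomies under heavy conflict — both visible as low MC resolution at
  high deletion ratios.
* BWD support functions beyond SAC/SACmax (SP, SC, SAP) are not
  implemented, and matrix-representation methods (MRP and relatives) are
  out of scope; the package targets the polynomial family only.
* Newick inputs are taken as rooted as written; genuinely unrooted inputs
  must be rooted explicitly via `root_at_outgroup()`.
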