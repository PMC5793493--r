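---
title: "Principal components in BHV tree space: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal components in BHV tree space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhvpca)
```

## The space and its geodesics

A rooted phylogenetic tree on leaves `{0, ..., N}` (leaf 0 acts as the
root) is encoded by its splits: each edge bipartitions the leaf set, and we
store the side away from the root, so the representation is unique.  All
trees with the same topology form a Euclidean orthant with one coordinate
per internal edge; orthants are glued along the boundaries obtained by
contracting edges.  The resulting Billera–Holmes–Vogtmann (BHV) space is
CAT(0): any two trees are joined by a unique geodesic, and Fréchet means
are unique.  Pendant edges contribute a Euclidean factor; following
standard practice in this kind of analysis, every statistic in the package
ignores pendant edges by default (`internal_only = TRUE`), while the
geometry with pendant edges included remains available.

Geodesics are computed by the polynomial-time geodesic tree path (GTP)
construction.  The support of the geodesic between `x` and `y` is a triple
`(A, B, C)`: ordered blocks `A^(1), ..., A^(l)` of splits of `x` that are
successively contracted, matching blocks `B^(1), ..., B^(l)` of splits of
`y` that appear, and the set `C` of splits compatible with everything in
both trees, which interpolate linearly.  The squared length is

    d(x, y)^2 = sum_l ( ||A^(l)|| + ||B^(l)|| )^2 + ||C_x - C_y||^2 .

Starting from the cone path (one block containing all incompatible
splits), a block is split whenever a minimum-weight vertex cover of its
bipartite incompatibility graph — with weights `|e|^2 / ||A||^2` and
`|f|^2 / ||B||^2`, solved by Edmonds–Karp max-flow — has weight below one.
Numerical choices: cover weights are compared with absolute tolerance
`1e-12`, and a cover of weight exactly one does **not** split the block
(the cone path over that block is already geodesic; this choice also gives
a canonical support for ties, such as the symmetric kinked geodesic of the
built-in `fixture_t5()` example).  A defensive guard keeps a block whole
if floating-point degeneracy (near-zero edge lengths) ever produces an
improper cover split.

Points along a geodesic use the standard parametrization: block `i`
vanishes at arc-length fraction `||A^(i)|| / (||A^(i)|| + ||B^(i)||)`,
the opposite block grows linearly beyond it, and common splits interpolate
linearly.  Arc-length additivity (`d(x, gamma(t)) = t d(x, y)`) is a
property test, not an assumption.

The test suite validates the whole construction against an independent
brute-force oracle that minimizes the length formula over all ordered
partitions satisfying *both* the valid-path compatibility condition and
the ratio ordering `||A^(1)||/||B^(1)|| <= ... <= ||A^(l)||/||B^(l)||`.
The ratio constraint is essential: by Cauchy–Schwarz the formula always
decreases under further splitting, so dropping the constraint would
"shortcut" kinked geodesics (for the `fixture_t5()` pair `v1, v2` it would
report `sqrt(18)` instead of the correct `2 sqrt(5)`).

## Weighted Fréchet means

The weighted Fréchet mean of vertices `V = {v_0, ..., v_k}` with weights
`p` on the simplex minimizes `Omega(x, p) = sum_i p_i d(x, v_i)^2`.  Two
iterative schemes are provided:

* **Sturm** (`method = "sturm"`): at iteration `i`, sample vertex `j` with
  probability `p_j` and move a fraction `1/(i+2)` along the geodesic
  towards it.
* **Cyclic** (`method = "bacak"`, the default): vertices are used in a
  fixed cycle `j = i mod (k+1)` and the weights enter through the step
  sizes, `s_i = p_j (k+1) / (i+2)`, clipped to `[0, 1]`.  For uniform
  weights this reduces exactly to the Sturm step; the two schemes are
  cross-checked against each other and against the closed-form Euclidean
  mean in single-orthant configurations.

Convergence is declared when the last `m` iterates (default `m = 5`) lie
pairwise within `eps` (default `1e-6` distance units).  The implementation
tests the *sum of the last `m - 1` step lengths*, which upper-bounds the
diameter of the window and costs nothing extra, because each step length
`s_i d(mu_i, v_j)` falls out of the geodesic computation already needed
for the move.  Empirically (calibrated on the closed forms of the
`fixture_t5()` configuration) the distance of the returned iterate from
the true mean is slightly below `eps`, so `eps` can be read as an accuracy
target; iteration counts scale like `max_j p_j d(mu, v_j) / eps`, which is
why coarse tolerances are used for bulk surveys and fine ones for
fixture-level checks (the defaults used by every study-scale computation
are stated with the corresponding function below).

On a region whose geodesics to all vertices are *simple* (each support
block a singleton: at most one edge contracts at a time), the
stationarity condition is linear and `local_affine_solution()` returns the
mean in closed form; the locus is an affine patch of dimension at most `k`
there.  For the `fixture_t5()` configuration this gives the plane
`xi = (p0 - 2 p1 + p2, p0 + p1 - 2 p2, 1 + p0)` — the second coordinate is
the symmetric completion, confirmed by solving the Euclidean stationarity
directly and by the iterative means — while in the non-simple ("curved")
region the mean follows the closed form with
`f(p) = (p0 + p1)/(p0 - 2 p1)`, whose signs were verified against the
iterative solver before being frozen into tests.

## The locus as a principal component

`Pi(V) = { mu(V, p) : p in S^k }` contains the vertices and all
vertex-pair geodesics, is compact, generally non-convex, and (for generic
vertices) is a `k`-dimensional surface: the natural analogue of a
`k`-th principal component for tree data.  Two projection algorithms are
provided.

* `project_exhaustive()` minimizes `d(z, mu(V, p))` over a triangular
  lattice on the weight simplex (default spacing 1/32; surveys use 1/16).
  It is the benchmark, not the workhorse.  Two numerical devices keep it
  affordable and accurate: (i) the lattice sweep runs at a coarse solver
  tolerance (`1e-2`) and only near-minimal candidates are recomputed at
  the fine tolerance; (ii) optional *local lattice refinement*
  (`refine_levels`) halves the lattice spacing around the best few cells
  (`refine_starts = 3`, caching repeated evaluations) so the benchmark
  reaches an effective resolution several times the global one at a
  fraction of the cost.  Both devices only affect solver error, which is
  kept far below the decision thresholds they feed.
* `project_geometric()` is the fast algorithm: a greedy variant of the
  Sturm iteration.  From the current estimate, candidates sit a fraction
  `1/(i+2)` along the geodesics towards each vertex; the candidate nearest
  the data tree is always adopted, and the returned weight vector counts
  how often each vertex was chosen.  The start is drawn uniformly by arc
  length from the perimeter of the locus (edges chosen proportionally to
  their geodesic lengths).  A `restarts` argument keeps the best of
  several starts (default 1, matching the benchmarked configuration).

Fit quality is summarized by the sum of squared projection distances
`D^2` and a non-Euclidean `r^2` built from the residual term
`R = sum_i d(z_i, pi(z_i))^2` and the dispersion term
`E = sum_i d(pi_bar, pi(z_i))^2`, where `pi_bar` is the Fréchet mean of
the projections.  Because Pythagoras fails in tree space the two terms do
not add up to a fixed total.  `r_squared()` defaults to the
"explained" form `E / (R + E)`, which behaves as a proportion of variance
explained (more dispersed residuals push it down); the "literal" form
`R / (R + E)` is also exposed since both appear in the literature-style
formulas and they disagree about which term sits in the numerator.  When
all projections coincide (stickiness can do this) the statistic is 0 and
flagged degenerate.  Stickiness also means the minimizing `p` need not be
unique even when the projected tree is; the reported `p` is the one found,
without a uniqueness claim.

### Validation of the projection algorithm

`validation_harness()` replicates the projection validation design: per
replication a species tree on 7 leaves is drawn from the Kingman
coalescent, four gene trees are simulated inside it under the
multispecies coalescent (three vertices and a test tree `z`), and `z` is
projected by both algorithms, ignoring pendant edges.  A replication
passes if (1) the geometric distance does not exceed the benchmark
distance plus half a lattice cell at the benchmark's effective resolution
(the natural slack for a lattice minimizer), and (2) the two projected
trees lie within 1% of `z`'s total internal length of each other.  The
benchmark uses the 1/16 lattice with three refinement levels
(effective 1/128), a coarse tolerance of `1e-2`, fine `1e-3`, and the
geometric projection runs at `1e-4` so that solver noise sits well below
both thresholds.

Under these conditions the harness passes roughly 80% of replications
(the exact figure for a given seed is computed by
`scripts/acceptance.R`).  The failures are informative: they are
dominated by configurations where the greedy iteration converges — from
*every* start point — to a locally stationary "pseudo-foot" that is not
the global minimizer of the perpendicular distance.  Restarting from
several perimeter locations therefore does not rescue these cases (a
monotone accept-only-improvements variant was evaluated and is much
worse, freezing early far from the foot).  Among failing replications the
geometric distance exceeds the benchmark by a few percent and the two
results disagree by several percent of the data tree's internal length;
these diagnostics are also recomputed by the acceptance script.

## Fitting the locus to data

`fit_locus()` performs greedy stochastic optimization over vertex
configurations for `k = 2`: each sweep visits the three vertices in turn
and draws one candidate from each proposal family — a uniform draw from
the data; a Beta(2,2) interpolation along the geodesic from the current
vertex to a random data tree; and random walks (defaults: one step at 20%
of the data's mean internal edge length, and five steps at 5%) — accepting
whenever `D^2` (geometric projections) decreases.  Candidate evaluation
abandons early once the partial sum exceeds the incumbent, which is what
makes the sweep affordable; no caching of projections across accepted
moves is attempted because a projection depends on the whole vertex set.
A run stops when the relative `D^2` improvement over a 10-sweep window
(surveys use 5) falls below `1e-3`; three independent runs are kept by
default (tests and the acceptance script use two, with `n = 30` data
trees, sizes chosen so the full suite stays comfortably within an
ordinary desktop budget).  Within a sweep an acceptance does not restart
the sweep; the scan simply continues with the next vertex/proposal pair.

## Synthetic data

All validation inputs are generated in code:

* `sim_species_tree()` — Kingman coalescent (waiting rate `j(j-1)/2`),
  times in coalescent units.
* `sim_gene_trees()` — multispecies coalescent constrained to a species
  tree: one lineage per species, within-branch coalescence at rate
  `j(j-1)/2`, survivors carried into the parent branch, free coalescence
  above the root.  Species-tree branch lengths are interpreted in
  coalescent units (the natural convention when both stages use the same
  clock).
* `random_tree_gamma()` — coalescent topology with i.i.d. Gamma(2, 20)
  edge lengths (mean 0.1).
* `nni()` / `spr()` — rearrangements on the split representation; edges
  that persist keep their lengths and the edge destroyed by pruning
  donates its length to the created edge, so total internal length is
  conserved.  Leaf prunes are included in `spr()` (every NNI is an SPR
  once they are), while the random generator `rspr()` draws internal
  prune edges, which is the variant used to build datasets.
* `random_walk_tree()` — isotropic Gaussian steps on the internal edge
  lengths; a coordinate crossing zero contracts its split and the walk
  re-enters one of the three orthants at that face uniformly (original
  split or either alternative resolution), carrying the overshoot.  The
  boundary rule is this package's construction — reflection or stopping
  at the boundary would be equally defensible — and is isolated behind
  this one function so alternatives can be swapped.
* `make_surface_dataset()` — the full recipe for a dataset scattered
  around a known locus: `w0` from the gamma model, `w1`, `w2` by NNI or
  SPR moves, weight vectors from Dirichlet(4,4,4), surface points by the
  cyclic mean, and random-walk perturbation.  Walk scales of 0.01
  (low dispersion) and 0.03 (high) against a mean edge length of 0.1 give
  clearly separated regimes: these were fixed once, from the
  edge-length scale, before any fitting experiments.

What the generators deliberately do not emulate: sequence-level noise and
gene-tree estimation error (data trees are exact draws from the model),
rate variation across lineages, and missing taxa.  Passing tests
therefore demonstrate the geometry and the optimization machinery, not
robustness to phylogenetic inference artifacts.

## Known limitations

* The greedy geometric projection has pseudo-foot attractors (above); for
  analyses where the benchmark matters, `project_exhaustive()` with local
  refinement is the reference.
* `fit_locus()` is restricted to `k = 2`, and its greedy search carries no
  global-optimality guarantee; multiple runs are essential.
* Leaf sets are limited to 31 non-root leaves (splits are bitmask-coded);
  within that range distances are exact to floating precision.
* The exhaustive benchmark's local refinement descends on the simplex and
  can in principle stop in a local basin of the distance-over-weights
  landscape; launching from several near-minimal cells mitigates but does
  not eliminate this.
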