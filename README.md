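# bhvpca

Principal component analysis for collections of phylogenetic trees,
carried out directly in the Billera–Holmes–Vogtmann (BHV) space of rooted
trees on a fixed leaf set.

Datasets of gene trees are high-dimensional and live in a space that is
not a vector space, so classical PCA does not apply.  In BHV space —
one Euclidean orthant per topology, glued along shared boundaries, and
globally CAT(0) — the analogue of the affine span of `k + 1` points
`V = {v_0, ..., v_k}` is the **locus of the weighted Fréchet mean**

```
Pi(V) = { mu(V, p) : p in S^k },   mu(V, p) = argmin_x sum_i p_i d(x, v_i)^2,
```

where `d` is the BHV geodesic distance and `S^k` the probability simplex.
`Pi(V)` contains the vertices and all vertex-pair geodesics and is
generically a `k`-dimensional surface, so minimizing the sum of squared
projection distances `D^2_Z(Pi(V)) = sum_i d(z_i, Pi(V))^2` over vertex
configurations yields a `k`-th principal component for tree data.

The package provides, with the hot loops in C++:

* exact BHV geodesics, distances and points along geodesics via the
  polynomial-time geodesic tree path (GTP) construction (min-weight
  vertex covers solved by max-flow);
* weighted Fréchet means (Sturm's stochastic scheme and a deterministic
  cyclic scheme), plus closed-form means on regions where all geodesics
  are simple;
* sampling of `Pi(V)`, exhaustive-benchmark and fast geometric projection
  of data trees onto it, and the summaries `D^2` and non-Euclidean `r^2`;
* fitting `Pi(V)` to a dataset by greedy stochastic optimization over
  vertex configurations with data-sample, geodesic-interpolation and
  random-walk proposals;
* simulation machinery for end-to-end validation: Kingman coalescent
  species trees, multispecies-coalescent gene trees, gamma-edge random
  trees, NNI/SPR rearrangements, tree-space random walks, and datasets
  scattered around a known locus;
* a command-line interface (`inst/scripts/bhvpca`) with subcommands
  `distance`, `geodesic`, `mean`, `project`, `fit`, `simulate`,
  `validate` and `simplex-map` for running the same workflow on
  user-supplied Newick files.

## Worked example

The built-in three-vertex configuration in the space of trees on six
leaves (`fixture_t5()`) has a fully understood locus: planar where the
geodesics to all vertices are simple, curved where the geodesic to `v2`
kinks around a codimension-2 face.

```r
library(bhvpca)
v <- fixture_t5()

bhv_distance(v$v1, v$v2)          # 4.472136 = 2 * sqrt(5): kinked cone path
g <- bhv_geodesic(v$v1, v$v2)
t5_coords(geodesic_point(g, 0.5)) # 0 0 1   : the cone point

m <- frechet_mean(v, c(0.6, 0.2, 0.2), eps = 1e-5, max_iter = 1e6)
round(t5_coords(m$mean), 4)       # 0.4 0.4 1.6 = (p0-2p1+p2, p0+p1-2p2, 1+p0)

z  <- parse_newick("((2:1,3:1):0.6,((4:1,5:1):0.2,1:1):3,0:1);")
pr <- project_geometric(z, v, seed = 1, eps = 1e-5)
pr
#> Projection: distance 4.0487228 at p = ( 0.0000, 0.4824, 0.5177 )
```

The projection returns the nearest point of the locus, the weight vector
that produces it, and the perpendicular distance.  Fitting a locus to a
simulated cloud of trees:

```r
ds  <- make_surface_dataset(n = 30, op = "nni", dispersion = "low", seed = 101)
fit <- fit_locus(ds$Z, seed = 7, runs = 2)
fit
#> Locus fit over 2 run(s):
#>   D^2 = 0.0797833   r^2 = 0.4541
```

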