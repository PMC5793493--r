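Package: bhvpca
Title: Principal Component Analysis in Billera-Holmes-Vogtmann Tree Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Geometry and statistics for collections of rooted phylogenetic
    trees viewed as points in the Billera-Holmes-Vogtmann (BHV) tree space.
    Computes geodesics and geodesic distances with the polynomial-time
    geodesic tree path (GTP) algorithm, weighted Frechet means by the Sturm
    and Bacak iterative schemes, and the locus of the weighted Frechet mean
    of k+1 vertex trees, which plays the role of a k-th principal component
    for tree-valued data. Data sets are projected onto the locus by an
    exhaustive lattice search or by a fast geometric projection algorithm,
    and the locus is fitted to data by greedy stochastic optimization over
    vertex configurations. Includes coalescent and multispecies-coalescent
    simulators, nearest-neighbour-interchange and subtree-prune-and-regraft
    rearrangements, and random-walk perturbations for validating the whole
    pipeline on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
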