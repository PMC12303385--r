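# venanet

Hydrodynamic modeling of full-scale leaf venation networks in R.

Leaf veins form planar transport networks — trees overlaid with loops —
that deliver water from the petiole (the xylem problem; the phloem problem
is its mathematical dual) to every part of the lamina. `venanet`
implements a complete pipeline for confronting hydrodynamic optimality
models with such networks at the level of individual veins:

* **Extraction**: binary vein-segmentation masks are skeletonized
  (Guo–Hall thinning plus a Euclidean distance transform for local
  widths), endpoints and branch points detected, edges traced and pruned,
  yielding a graph with per-edge lengths and widths; per-node drainage
  areas come from a Voronoi tessellation clipped to the leaf boundary
  (alpha shape or supplied polygon).
* **Flow**: steady laminar (Hagen–Poiseuille) flow, conductivity
  `c = w^4`, solved through the weighted graph Laplacian
  `A = B C_eff B^T` with a sparse Cholesky factorization reused across an
  ensemble of area-weighted fluctuating sink loads `s(k)` parameterized by
  the sink fluctuation amplitude `sigma` in `[0, 1]`.
* **Optimization**: edge conductivities minimizing dissipation
  `P = sum f_i^2 / c_eff_i` at fixed material cost `sum l_i c_i^gamma`
  (default `gamma = 1/2`, a fixed-volume budget) via the fixed-point
  iteration `c <- <f^2>^(1/(1+gamma))`, initialized at the observed widths
  so the local optimum nearest the data is selected; k-means subsystem
  decomposition for large leaves.
* **Inference**: the amplitude `sigma` fitted by edge-to-edge width
  comparison, `L(sigma) = <(w_data - w_model)^2 / w_data>`; and an
  extended Murray's law for reticulate networks,
  `R_in(alpha) = R_out(alpha)` with direction-resolved radius sums
  averaged over the sink ensemble, giving a fitted branching exponent
  `alpha*` (classically 3).
* **Synthetic leaves**: jittered triangular lattices on an elliptic
  lamina, model-generated pseudo-data for parameter recovery, and mask
  rendering for extraction round trips.

## Worked example

```r
library(venanet)

# a synthetic leaf: ellipse 2 x 1, ~510 nodes, loopy triangular lattice
leaf <- generate_leaf_lattice(leaf_shape(spacing = 0.06, seed = 0))
leaf
#> <venation_graph> 510 nodes, 1441 edges, source node 510
#>   widths: mean 0.9998, range [0.99, 1.01], 0 zero
#>   drainage areas: total 1.57017

# optimize without sink fluctuation: the optimum is a spanning tree
fit0 <- optimize_conductivities(leaf, optimizer_config(sigma = 0))
fit0
#> <venation_fit> sigma = 0, gamma = 0.5: converged after 43 iterations
#>   509 of 1441 edges with positive model width (cycle rank 0)

# Murray exponent of the tree: the classical value 3
fa <- fit_alpha(leaf, fit0$widths_model, sink_ensemble(leaf, 0))
fa
#> <murray_fit> alpha* = 2.9853 (bracketed), 48 branch nodes, L(alpha*) = 0.05844

# with sink fluctuation, loops survive and the exponent shifts upward
fit1 <- optimize_conductivities(leaf, optimizer_config(sigma = 0.094))
cycle_rank(leaf, fit1$widths_model > 0)
#> [1] 60
fit_alpha(leaf, fit1$widths_model, sink_ensemble(leaf, 0.094),
          alpha_grid = seq(2.5, 4, 0.01))$alpha_star
#> [1] 3.018246
```

The `2.99`-vs-`3` gap is real, not noise: the model drains fluid at every
node, so even a perfect tree misses the leak-free law by a per-node
deficit proportional to the node's drainage area (all residuals negative;
correcting each by a fitted `kappa * a_b` drives them to zero). The bias
shrinks as `1/n` with network size. Parameter recovery works the same way
in reverse: pseudo-data generated at `sigma = 0.3` with 10% lognormal
width noise hand back `sigma* = 0.30` from `fit_sigma()`.

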