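---
title: "Hydrodynamic modeling of leaf venation networks with venanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrodynamic modeling of leaf venation networks with venanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venanet)
```

## The model

A leaf venation network is represented as a directed planar graph with
`n_n` nodes and `n_e` edges; each edge carries a length `l_i` and a width
`w_i`, and one node — the petiole — injects fluid that the remaining nodes
drain. Treating each vein as a cylindrical pipe with laminar flow, the flux
through edge `i` is given by the Hagen–Poiseuille law

    f_i = (c_i / l_i) * (p_tail - p_head),        c_i = w_i^4,

so that with the signed incidence matrix `B` (one `+1` and one `-1` per
column) and the diagonal conductance matrix `C_eff = diag(c_i / l_i)`,
mass conservation `B f = s` leads to the weighted graph Laplacian system

    A p = s,   A = B C_eff B^T,   f = C_eff B^T p.

`A` has rank `n_n - 1` on a connected graph; `venanet` fixes the pressure
gauge by grounding the source node and solving the reduced
symmetric-positive-definite system with a sparse Cholesky factorization
(`Matrix`/CHOLMOD). The factorization is computed once per conductivity
state and reused for every load vector, with one step of iterative
refinement, so the conservation residual stays far below the contractual
`1e-9 * max|s|`.

### Fluctuating, area-weighted sinks

Real leaves drain heterogeneously: each node is assigned a drainage area
`a_j`, the area of its Voronoi cell clipped to the leaf boundary, and the
drainage demand fluctuates in time. Both effects enter through an ensemble
of load vectors parameterized by a moving sink node `k`:

    s_source = 1
    s_j(k)   = -a_j (s_avg + delta_jk * sigma) * C(k)     otherwise,

with `s_avg = (1 - sigma) / (n_n - 1)` and
`C(k) = (sigma a_k + s_avg * sum_j a_j)^-1`, which makes every member sum
to zero exactly. The sink fluctuation amplitude `sigma` interpolates
between purely area-proportional drainage (`sigma = 0`, all members
identical) and a fully concentrated moving sink (`sigma = 1`, where
`s_k = -1` and all other sinks vanish). Squared fluxes are averaged
uniformly over all `n_n - 1` sink positions:

    <f_i^2> = (1 / (n_n - 1)) * sum_k f_i^2(s(k)).

Averaging the *squares* is what distinguishes a fluctuating-sink model
from a static one, and is what lets loops survive optimization.

### Optimal conductivities

The network is assumed to minimize the dissipated power
`P = sum_i f_i^2 / c_eff_i` at fixed material cost `sum_i l_i c_i^gamma`.
The Lagrange condition gives `c_i ~ |f_i|^(2 / (1 + gamma))`, which
`venanet` solves by the fixed-point iteration

    f(n+1) = G(n) s,     c(n+1) = <f(n+1)^2>^(1 / (1 + gamma)),

initialized at the observed widths, `c(0) = w_data^4`. The landscape is
highly non-convex — different small perturbations of a uniform state end
in topologically different optima — so the data initialization is not a
convenience but the selection rule: the iteration converges to the local
optimum nearest the observed network. Conductivities are kept in arbitrary
units throughout; output widths `w = c^(1/4)` are rescaled once at the end
to match the mean observed width, and normalized widths below
`1e-3 * mean(w_data)` are reported as exactly zero.

The default `gamma = 1/2` makes the budget `sum l c^(1/2) = sum l w^2`
proportional to total vein volume. At `gamma = 1/2` a converged network
obeys `w^3 ~ |f|` edge by edge — Murray's law with exponent 3 — which is
the basis of the analyses below.

### Numerical choices

* **Convergence** is declared when the per-edge relative conductivity
  change drops below `tol` (default `1e-6`) on every *surviving* edge.
  Surviving means a width above one tenth of the zero-classification
  cutoff: edges below that are decaying double-exponentially (a dying
  edge's relative change stays O(1) all the way down, so a global
  criterion would never terminate, while a max-normalized criterion stops
  while visible edges are still moving). The safety decade guarantees the
  iteration cannot stop while an edge that would be *reported* nonzero is
  still dying.
* **Zero conductances** are floored at `1e-20 * max(c)` when assembling
  the Laplacian — far enough below the `1e-3` width cutoff (a floor of
  `eps * max(c)` corresponds to widths of `eps^(1/4) * w_max`) that
  floor-limited edges can never straddle the classification boundary. If
  rounding ever pushes a pivot of the analytically-SPD reduced Laplacian
  nonpositive (possible when a whole neighborhood sits at the floor), the
  solver retries that factorization with a temporarily raised floor; the
  stored conductivities are untouched.
* **Determinism**: all generators take explicit seeds and restore the
  caller's RNG state; k-means partitions, tie-breaks and iteration orders
  are fixed by cluster index.

## Subsystem decomposition

Full leaves have `10^4`–`10^5` nodes, too many to factorize at every
iteration. Because the data initialization starts near the optimum, a
local change has limited range, so the leaf is split into `K` (~10)
k-means clusters of nodes and each cluster's interior edges are optimized
separately with all exterior conductivities frozen. A full-system load `s`
is translated to a subsystem load by adding the net flow entering through
the crossing edges, `s~ = M (I - J G) s = Z s`, where `J` holds the
incidence entries of crossing edges at subsystem nodes and `M` selects the
subsystem rows. `G` and all `Z` are computed once, at the initial
conductivities. With frozen conductivities the subsystem solve
`f~ = G~ Z s` reproduces the full-system fluxes on interior edges to
machine precision, and with `K = 1` the subsystem optimizer reproduces the
monolithic one bit for bit.

One unit-consistency choice is ours: the fixed point lands in flux units
while frozen crossing edges stay in data units, so after each subsystem
converges its interior conductivities are rescaled back to the subsystem's
initial material budget (`sum l c^gamma`). Within a subsystem the scale is
arbitrary — uniform rescaling leaves all flows unchanged — and this keeps
every edge of the leaf commensurate for the single final width
normalization. Near the optimum the decomposition is tight: on a
pseudo-data leaf, `K = 4` agrees with the monolithic result to well under
1% RMS in the widths. Far from the optimum (e.g. uniform initial widths)
the frozen-exterior approximation is *not* expected to agree, which is why
the package applies it in the data-initialized regime it was designed for.
Crossing edges belong to no interior and keep their data widths; one sweep
over subsystems is the default, matching the one-shot computation of `Z`.

## Fitting the sink fluctuation amplitude

The model output can be compared to the data edge by edge:

    L(sigma) = < (w_data_i - w_hat_i(sigma))^2 / w_data_i >_i,

the squared difference weighted by inverse width, which gives every vein
pixel of the original image equal weight. `fit_sigma()` evaluates the loss
on a grid (default `0, 0.02, ..., 0.30`, concentrated at the small
amplitudes where leaf optima lie) and refines the argmin parabolically.
Every grid evaluation restarts from the data widths rather than from the
neighboring solution: each `sigma` must be scored at the local optimum
nearest the data, not at a continuation of someone else's optimum. A
consequence worth knowing: if the data widths themselves form a tree, that
tree is a fixed point at *every* `sigma` (dead loop edges cannot regrow
under the multiplicative update), so all grid points converge quickly and
the loss still ranks `sigma = 0` best — the recovery tests exercise
exactly this behavior.

## Murray's law for reticulate networks

Classical Murray's law — parent radius cubed equals the sum of daughter
radii cubed — is only defined on trees. With fluctuating sinks the in/out
role of each vein at a branch node depends on the sink position, so the
law is extended by averaging direction-resolved radius sums over the
ensemble:

    R_b_in/out(alpha) = < sum_i I_b_i_in/out(k) * r_i^alpha >_k,

with the law `R_b_in = R_b_out` and the loss
`L(alpha) = <(R_b_out - R_b_in)^2>_b` over branch nodes (degree > 2 among
positive-width edges). Because radii are independent of `k`, the average
factorizes exactly into per-edge direction fractions, which is how
`murray_sums()` computes it. Fluxes below `1e-12 * max|f|` count to
neither direction. Radii are `w/2` by default; using widths instead
multiplies both sums by `2^alpha` and leaves the fitted exponent unchanged
(tested). The source node is excluded from the branch set: it carries the
net injection, so its sums cannot balance — in extracted leaves the
petiole is a single entering vein and the case never arises, but on
synthetic lattices the petiole connects to several neighbors.

Even a perfect tree violates the leak-free law, because fluid leaves at
every node: at the `gamma = 1/2` fixed point `w^3 ~ |f|` and conservation
leaves a deficit exactly proportional to the node's own sink, so all
residuals are negative and `residual_b = -kappa * a_b` with a single
global `kappa`. `sink_corrected_residuals()` fits `kappa` in closed form;
on a converged tree the corrected residuals vanish to the optimizer
tolerance. The finite leak also pulls the fitted exponent slightly below
3 — each branch node balances at an exponent below 3 by an amount of order
its sink-to-flux ratio, i.e. O(1/n) — so the exponent converges to 3 from
below as the lattice grows; at the ~500-node study size it lands within
±0.05. With nonzero `sigma` the width hierarchy flattens and the optimum
shifts to values at or above 3, while residuals spread and shift positive
relative to the tree case.

A related caveat: the argmin of the raw loss `L(alpha)` is strictly scale
invariant only where the minimum is exactly zero (a global width rescale
multiplies `L` by `lambda^(2 alpha)`). Near a deep minimum the induced
shift is far below the grid resolution, and the leak-free Y fixture pins
the exact case in the tests.

## Extraction from binary masks

The pipeline mirrors standard practice: Guo–Hall thinning produces a
one-pixel, 8-connected centerline (chosen over Zhang–Suen, whose staircase
artifacts on thick oblique strokes shatter junctions into branch-point
webs); local width is read from the Euclidean distance transform as
`2 d - 1` pixels (the `-1` accounts for pixel-center offset, making an
axis-aligned bar of thickness `k` report exactly `k`); endpoints and
branch points come from 8-neighbor counts, with adjacent branch pixels
merged at their centroid; edges are traced by walking chains between node
pixels (step cost 1 or sqrt(2)), their width a high quantile of the
per-pixel widths after trimming half a vein width at each end, where the
distance transform is inflated by the junction. Pruning merges nodes
within `merge_radius` (3 px), contracts junction stubs — edges shorter
than twice their own width, which no genuine vein segment can be — and
removes degree-2 nodes by concatenating edges (length-weighted width).
Pruning is idempotent. Drainage areas come from a Dirichlet tessellation
clipped to the leaf boundary (an alpha shape of the node cloud by default,
built from the Delaunay triangulation with the smallest circumradius
threshold that yields one simple polygon covering 99% of nodes; convex
hull as fallback).

## The synthetic generator

Synthetic leaves stand in for image-extracted networks: a triangular
lattice (abundant loops and degree-6 branch nodes) clipped to an elliptic
lamina, node positions jittered by 20% of the spacing to emulate
extraction non-uniformity, a petiole appended at the base and connected to
its three nearest nodes, initial widths uniform with a 1% multiplicative
perturbation, and drainage areas from the known boundary. The study
lattice used by the acceptance experiments is an ellipse of total length 2
and width 1 at spacing 0.06 (about 510 nodes, seed 0); the
parameter-recovery experiments use spacing 0.08 (about 280 nodes), sizes
at which the full experiments run in minutes on one CPU while the
finite-size Murray bias stays within the tested band. Pseudo-data for
recovery tests are produced by the model itself at a known `sigma`, with
lognormal width noise and a floor at `1e-3` of the mean width (real
extracted networks contain no zero-width edges). What the generator does
*not* emulate: vein-order hierarchy from growth, anisotropic major veins,
segmentation errors, and the degree-3-dominated junctions of real leaves —
so passing tests validate the machinery and the model's internal
consistency, not biological realism.

## Worked example

```{r example, eval = FALSE}
library(venanet)

shape <- leaf_shape(length = 2, width = 1, spacing = 0.06, seed = 0)
leaf <- generate_leaf_lattice(shape)

fit <- optimize_conductivities(leaf, optimizer_config(sigma = 0))
sum(fit$widths_model > 0)     # n_nodes - 1: a spanning tree
cycle_rank(leaf, fit$widths_model > 0)   # 0

ens <- sink_ensemble(leaf, 0)
fa <- fit_alpha(leaf, fit$widths_model, ens)
fa$alpha_star                 # ~2.99

fit_loopy <- optimize_conductivities(leaf, optimizer_config(sigma = 0.094))
cycle_rank(leaf, fit_loopy$widths_model > 0)  # > 0: loops retained
```

## Known limitations

* The synchronous fixed-point map can possess stable reticulate fixed
  points even at `sigma = 0` on fine lattices; with the data (or
  perturbed-uniform) initialization used here the iteration reaches trees,
  but global optimality is never claimed — by design, only the local
  optimum nearest the initialization.
* Murray exponents carry a finite-size leak bias of order 1/n; compare
  exponents only between networks of similar size.
* Width estimates from 5-px rasterized strokes are accurate to roughly
  10-15%; below 3 px they are unreliable.
* The sigma fit is a single-parameter fit; `gamma` is held at 1/2 and may
  in reality vary between species.
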