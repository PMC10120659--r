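# diffeost

Diffeomorphic metric mapping alignment of spatial transcriptomics (ST) data
in R.

## The problem

Comparing ST datasets across sections, samples and technologies requires
placing them in a common spatial frame. Tissue sections are rotated,
stretched, torn and only partially overlapping, so rigid or affine
registration is not enough, and section-to-section comparisons need local,
non-linear — but still invertible — deformations. `diffeost` solves this with
large deformation diffeomorphic metric mapping (LDDMM) on *cell-density
images*: datasets with tens to hundreds of thousands of cells are first
rasterized, so the cost of each solver iteration scales with the number of
pixels, not cells.

It is intended for computational biologists aligning single-cell-resolution
ST data (MERFISH, Xenium, STARmap, ...) to other sections, to histology
images backing multi-cellular technologies (Visium), or to a 3D reference
atlas with voxel-level region annotations.

## The model

Cell positions are treated as a point measure `rho` and smoothed into an
image `I = k_sigma * rho` by Gaussian convolution at a chosen pixel size
`dx` (default 30 µm). A source image `I_S` is aligned to a target `I_T` by a
map

    phi_{A,v}(x) = A( phi1_v(x) )

composed of a diffeomorphism `phi1_v` — the time-1 flow of a velocity field
`v_t` integrated over `t ∈ [0, 1]` — and an affine transform `A`. The
parameters minimize

    E(A, v) = R(v) + M_theta(phi_{A,v} · I_S, I_T) + 1/(2 sigma_P^2) Σ_i |A phi1_v(s_i) − t_i|²

where

* `R(v) = 1/(2 sigma_R^2 nt) Σ_t Σ_x |L v_t|² dx^d` with
  `L = (id − a² Δ)^p` penalizes rough velocity fields (`a` = 500 µm, `p` = 2
  by default), guaranteeing the flow stays diffeomorphic;
* `M_theta = 1/(2 sigma_M^2) Σ_x W(x) | f_theta(I_S ∘ phi^{-1})(x) − I_T(x) |² dx^d`
  is a robust weighted matching term: `f_theta` is a polynomial contrast
  transform reconciling intensity scales across modalities, and `W(x)` is the
  posterior probability that target pixel `x` belongs to the *matching*
  component of a three-component Gaussian mixture (matching / background /
  artifact), re-estimated by EM every epoch so missing tissue and artifacts
  are explained away instead of dragging the map;
* the optional last term penalizes distances between paired landmarks.

Optimization is steepest gradient descent with separate step sizes for the
linear part (`epL`), translation (`epT`) and velocity field (`epV`), the
velocity gradient being smoothed by the inverse Sobolev operator (natural
gradient). Gradients are exact hand-derived adjoints of the discrete
computation and are verified against finite differences in the test suite.
Once solved, the map transforms the original cell coordinates; the inverse
map resamples images and lifts 3D atlas annotations onto 2D cells
(`run_lddmm_3d_to_2d`, `lift_over_labels`).

## Worked example

Align a synthetic 5,000-cell tissue to a deformed copy of itself (rotation
15°, scale 1.05, translation (300, −200) µm plus smooth 150 µm bumps), then
measure recovery against the known ground truth:

```r
library(diffeost)

tissue <- generate_tissue(synthetic_spec(), seed = 42)   # 5000 cells, 8 blobs, 29 types
truth  <- deformation_spec(rotation = 15, scale = 1.05, translation = c(300, -200),
                           bump_centers = rbind(c(-900, 600), c(800, -300)),
                           bump_amps    = rbind(c(150, 40), c(-60, 130)),
                           bump_scale   = 600)
moved  <- deform_points(tissue, truth)

src <- normalize_image(rasterize(tissue, dx = 50))
tgt <- normalize_image(rasterize(moved,  dx = 50))
res <- run_lddmm(src, tgt, solver_config(dx = 50, niter = 400,
                                         diffeo_start = 50, epT = 0.05, epV = 1e3))
res
#> alignment_result: 2D source, 400 epochs, objective 97513 -> 2568.9

aligned <- transform_points(res, tissue, "forward")
mean(sqrt(rowSums((aligned$coords - moved$coords)^2)))
#> [1] 7.266067
```

The printed objective falls by a factor of ~38 over 400 epochs and the mean
distance between the aligned cells and their true deformed positions is
7.3 µm — a seventh of the 50 µm pixel size, versus a 32.7 µm residual for an
affine-only solve of the same problem. `matching_mask(res, points = tissue)`
flags, per cell, whether it landed in tissue the mixture model considers
matched (posterior > 0.85), which is how partially overlapping sections are
restricted to their shared region before downstream comparisons with
`grid_aggregate`, `cpm_log_normalize` and `cosine_similarity_per_feature`.

A command-line surface wrapping the same functions is installed at
`exec/diffeost` (subcommands `simulate`, `rasterize`, `align`, `align3d`,
`transform-points`, `liftover`, `evaluate`).

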