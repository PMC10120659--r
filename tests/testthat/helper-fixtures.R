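# Shared fixtures. Everything is generated in code at test time; heavier
# solved alignments are cached per session so several tests can share them.

tiny_tissue <- function(n = 300, seed = 3) {
  generate_tissue(synthetic_spec(n_cells = n, domain = 1500, n_blobs = 3,
                                 n_types = 5, n_genes = 4), seed = seed)
}

# A smooth random velocity field with controlled maximum magnitude.
smooth_test_velocity <- function(axes, nt = 3, max_v = 100, seed = 4,
                                 a = 500, p = 2) {
  vf <- zero_velocity(axes, nt = nt, a = a, p = p)
  set.seed(seed)
  vf$v[] <- stats::rnorm(length(vf$v))
  vf$v <- smooth_gradient(vf$v, axes, 300, 2)
  vf$v <- vf$v * (max_v / max(abs(vf$v)))
  vf
}

test_axes_2d <- function(lim = 800, dx = 50) {
  lapply(1:2, function(j) seq(-lim, lim, by = dx))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Standard recovery fixture: 5000-cell tissue under the study deformations.
study_tissue <- function() cached("study_tissue", generate_tissue(synthetic_spec(), seed = 42))

study_affine_spec <- function() deformation_spec(rotation = 15, scale = 1.05,
                                                 translation = c(300, -200))

study_bump_spec <- function() deformation_spec(
  bump_centers = rbind(c(-900, 600), c(800, -300), c(0, -900)),
  bump_amps = rbind(c(150, 40), c(-60, 130), c(90, -100)),
  bump_scale = 600)

# Solves shared between the diffeomorphic-recovery, diffeomorphism-property
# and objective-behavior tests (computed once per test run).
diffeo_solves <- function() cached("diffeo_solves", {
  ps <- study_tissue()
  ps2 <- deform_points(ps, study_bump_spec())
  src <- normalize_image(rasterize(ps, dx = 50))
  tgt <- normalize_image(rasterize(ps2, dx = 50))
  affine_only <- run_lddmm(src, tgt, solver_config(dx = 50, niter = 400,
                                                   diffeo_start = 400,
                                                   epT = 0.05))
  full <- run_lddmm(src, tgt, solver_config(dx = 50, niter = 400,
                                            diffeo_start = 50, epT = 0.05,
                                            epV = 1e3))
  list(ps = ps, ps2 = ps2, src = src, tgt = tgt,
       affine_only = affine_only, full = full)
})

mean_correspondence_error <- function(result, ps_src, ps_tgt) {
  tp <- transform_points(result, ps_src, "forward")
  mean(sqrt(rowSums((tp$coords - ps_tgt$coords)^2)))
}

# 3D atlas-like fixture: intensity volume, labels, and an exact axial slice.
vol_fixture <- function() cached("vol_fixture", {
  vol <- generate_volume(dims = c(20, 32, 32), dx = 50, n_blobs = 4, seed = 11)
  k0 <- 12
  z0 <- vol$intensity$axes[[1]][k0]
  slice_vals <- vol$intensity$values[k0, , , 1]
  tgt <- raster_image(array(slice_vals, c(32, 32)), vol$intensity$axes[2:3])
  list(vol = vol, k0 = k0, z0 = z0, tgt = tgt)
})
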