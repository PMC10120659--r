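# The solver's hand-derived adjoint gradients are checked against central
# finite differences of the objective (holding mixture weights and contrast
# coefficients fixed, as the descent itself does).
test_that("analytic gradients agree with finite differences", {
  ps <- generate_tissue(synthetic_spec(n_cells = 400, domain = 1500,
                                       n_blobs = 3, n_types = 4, n_genes = 3),
                        seed = 3)
  src <- normalize_image(rasterize(ps, dx = 100))
  dsp <- deformation_spec(rotation = 8, scale = 1.02, translation = c(60, -40),
                          bump_centers = matrix(c(200, 100), 1, 2),
                          bump_amps = matrix(c(80, -60), 1, 2),
                          bump_scale = 400)
  tgt <- normalize_image(rasterize(deform_points(ps, dsp), dx = 100))

  v_axes <- diffeost:::pad_axes(src$axes, 2)
  vf <- smooth_test_velocity(v_axes, nt = 3, max_v = 60, seed = 8)
  A_ax <- affine_transform(L = matrix(c(1.05, 0.08, -0.06, 0.97), 2, 2),
                           T = c(30, -20))
  ew <- energy_weights(sigma_M = 0.5, sigma_R = 5e4, sigma_P = 10)
  tgt_pts_ax <- matrix(diffeost:::grid_coords(tgt$axes),
                       prod(lengths(tgt$axes)), 2)
  tgt_y <- diffeost:::as_value_matrix(tgt)
  set.seed(9)
  w_match <- runif(nrow(tgt_y))
  lm_ax <- list(s = matrix(runif(6, -400, 400), 3, 2),
                t = matrix(runif(6, -400, 400), 3, 2))
  fw <- diffeost:::align_forward(A_ax, vf, src$values, src$axes, tgt_pts_ax)
  theta <- fit_contrast(fw$pred_raw, tgt_y, w_match, 3)
  pixvol <- prod(tgt$dx)

  Efun <- function(A_ax, vf) {
    diffeost:::energy_and_grads(A_ax, vf, src$values, src$axes, tgt_pts_ax,
                                tgt_y, w_match, theta, ew, pixvol,
                                lm_ax = lm_ax, with_grads = FALSE)$total
  }
  eg <- diffeost:::energy_and_grads(A_ax, vf, src$values, src$axes,
                                    tgt_pts_ax, tgt_y, w_match, theta, ew,
                                    pixvol, lm_ax = lm_ax)
  expect_true(is.finite(eg$total))

  # affine entries
  h <- 1e-6
  for (ij in list(c(1, 1), c(2, 1), c(1, 3), c(2, 3))) {
    Ap <- A_ax$matrix; Am <- A_ax$matrix
    step <- h * max(1, abs(Ap[ij[1], ij[2]]))
    Ap[ij[1], ij[2]] <- Ap[ij[1], ij[2]] + step
    Am[ij[1], ij[2]] <- Am[ij[1], ij[2]] - step
    fd <- (Efun(affine_transform(matrix = Ap), vf) -
             Efun(affine_transform(matrix = Am), vf)) / (2 * step)
    expect_equal(eg$gA[ij[1], ij[2]], fd,
                 tolerance = 1e-4 * max(1, abs(fd)))
  }

  # velocity field along random directions
  set.seed(10)
  for (rep in 1:2) {
    dv <- array(rnorm(length(vf$v)), dim(vf$v))
    hv <- 1e-4
    vp <- vf; vp$v <- vf$v + hv * dv
    vm <- vf; vm$v <- vf$v - hv * dv
    fd <- (Efun(A_ax, vp) - Efun(A_ax, vm)) / (2 * hv)
    expect_equal(sum(eg$gv * dv), fd, tolerance = 1e-4 * abs(fd))
  }
})

test_that("aligning an image to itself is a fixed point", {
  ps <- tiny_tissue(500, seed = 6)
  src <- normalize_image(rasterize(ps, dx = 50))
  cfg <- solver_config(dx = 50, niter = 100, epT = 0.05)
  res <- run_lddmm(src, src, cfg)
  lh <- res$loss_history
  # already optimal at epoch 1: allow a round-off floor
  expect_lte(lh$total[nrow(lh)], lh$total[1] + 1e-12)
  expect_lt(sqrt(sum(res$A$T^2)), 50 / 2)
  expect_lt(max(abs(res$A$L - diag(2))), 0.02)
  expect_lt(max(abs(res$v$v)), 50 / 2)
})

test_that("loss history is deterministic and complete", {
  ps <- tiny_tissue(300, seed = 7)
  src <- normalize_image(rasterize(ps, dx = 100))
  tgt <- normalize_image(rasterize(
    deform_points(ps, deformation_spec(translation = c(60, -30))), dx = 100))
  cfg <- solver_config(dx = 100, niter = 25, epT = 0.05)
  r1 <- run_lddmm(src, tgt, cfg)
  r2 <- run_lddmm(src, tgt, cfg)
  expect_identical(r1$loss_history, r2$loss_history)
  expect_identical(nrow(r1$loss_history), 25L)
  expect_true(all(is.finite(as.matrix(r1$loss_history))))
  expect_lt(max(abs(rowSums(r1$W$posteriors) - 1)), 1e-12)
})

test_that("solver honors configured initial guesses and rejects conflicts", {
  expect_error(solver_config(A0 = diag(3), T0 = c(1, 2)), "not both")
  cfg <- solver_config()
  expect_equal(cfg$dx, 30)
  expect_equal(cfg$sigma_R, 5e5)
  expect_equal(cfg$niter, 5000L)
  expect_equal(cfg$nt, 3L)
  expect_equal(cfg$epL, 2e-8)
  expect_equal(cfg$epV, 2e3)

  ps <- tiny_tissue(200, seed = 8)
  src <- normalize_image(rasterize(ps, dx = 100))
  cfg2 <- solver_config(dx = 100, niter = 2, epL = 0, epT = 0, epV = 0,
                        L0 = matrix(c(1.1, 0, 0, 0.9), 2, 2), T0 = c(5, -7))
  res <- run_lddmm(src, src, cfg2)
  expect_equal(res$A$T, c(5, -7), tolerance = 1e-10)
  expect_equal(res$A$L, matrix(c(1.1, 0, 0, 0.9), 2, 2), tolerance = 1e-10)
})

test_that("matching mask thresholds posteriors and flags outside points", {
  ps <- tiny_tissue(200, seed = 9)
  src <- normalize_image(rasterize(ps, dx = 100))
  cfg <- solver_config(dx = 100, niter = 5, epT = 0.02)
  res <- run_lddmm(src, src, cfg)
  mm <- matching_mask(res, threshold = 0.85, points = ps)
  expect_equal(dim(mm$mask), unname(lengths(res$target_axes)))
  expect_equal(mm$threshold, 0.85)
  expect_length(mm$point_flags, n_points(ps))

  # W_match identically 1 -> every pixel true
  res2 <- res
  res2$W$posteriors[, 1] <- 1
  expect_true(all(matching_mask(res2)$mask))

  # a point far outside the target grid is never matched
  far <- point_set(rbind(c(1e6, 1e6), ps$coords[1, , drop = FALSE]))
  flags <- matching_mask(res2, points = far)$point_flags
  expect_false(flags[1])
})
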