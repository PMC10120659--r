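test_that("landmark least squares recovers exact and noisy affines", {
  # identical source/target -> identity
  s <- rbind(c(0, 0), c(100, 0), c(0, 100))
  A <- fit_affine_landmarks(landmark_set(s, s))
  expect_lt(max(abs(A$matrix - diag(3))), 1e-10)

  # exact rotation + translation is recovered to round-off
  th <- 30 * pi / 180
  L <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  T <- c(100, -50)
  set.seed(2)
  s2 <- matrix(runif(10, -500, 500), 5, 2)
  t2 <- sweep(s2 %*% t(L), 2, T, "+")
  A2 <- fit_affine_landmarks(landmark_set(s2, t2))
  expect_lt(max(abs(A2$L - L)), 1e-8)
  expect_lt(max(abs(A2$T - T)), 1e-8)

  # noisy fit equals the direct normal-equations solution
  set.seed(3)
  t3 <- t2 + matrix(rnorm(10, sd = 5), 5, 2)
  A3 <- fit_affine_landmarks(landmark_set(s2, t3))
  X <- cbind(s2, 1)
  M <- solve(t(X) %*% X, t(X) %*% t3)
  expect_lt(max(abs(t(M[1:2, ]) - A3$L)), 1e-8)
  expect_lt(max(abs(M[3, ] - A3$T)), 1e-8)
  expect_equal(attr(A3, "rss"), sum((X %*% M - t3)^2), tolerance = 1e-10)

  # collinear landmarks are rejected with advice
  sc <- cbind(1:4, 2 * (1:4))
  expect_error(fit_affine_landmarks(landmark_set(sc, sc)), "degenerate")
})

test_that("velocity integration: zero field, constant field, step refinement", {
  axes <- test_axes_2d()
  X <- diffeost:::grid_coords(axes)

  vf0 <- zero_velocity(axes, nt = 3)
  expect_equal(integrate_velocity(vf0, "forward")$positions, X)
  expect_equal(integrate_velocity(vf0, "backward")$positions, X)

  # constant field: exact translation by (c, 0) for any nt
  for (nt in c(1, 3, 7)) {
    vfc <- zero_velocity(axes, nt = nt)
    vfc$v[, , 2, ] <- 120 # x-component in axis order (y, x)
    phi <- integrate_velocity(vfc, "forward")
    expect_lt(max(abs(phi$positions[, , 1] - X[, , 1])), 1e-10)
    expect_lt(max(abs(phi$positions[, , 2] - (X[, , 2] + 120))), 1e-10)
  }

  # smooth (in space and time) field: error vs a fine-step reference
  # shrinks roughly like 1/nt, the first-order Euler rate
  pattern <- smooth_test_velocity(axes, nt = 1, max_v = 120, seed = 4)
  mk <- function(nt) {
    vf <- zero_velocity(axes, nt = nt)
    for (t in seq_len(nt)) {
      tm <- (t - 0.5) / nt
      vf$v[, , , t] <- pattern$v[, , , 1] * (1 + 0.5 * sin(pi * tm))
    }
    vf
  }
  ref <- integrate_velocity(mk(192), "forward")$positions
  err <- function(nt) max(abs(integrate_velocity(mk(nt), "forward")$positions - ref))
  e3 <- err(3); e6 <- err(6); e12 <- err(12)
  expect_lt(e3, 0.15 * 120)
  expect_gt(e3 / e6, 1.4) # consistent with O(1/nt)
  expect_gt(e6 / e12, 1.4)
})

test_that("apply_map_to_points composes the flow and the affine", {
  ps <- tiny_tissue(100)
  axes <- test_axes_2d(1200, 100)
  # identity everything -> bit-identical coordinates
  idm <- diffeost:::identity_map(axes)
  out <- apply_map_to_points(NULL, idm, ps)
  expect_identical(out$coords, ps$coords)

  # pure affine matches direct matrix multiplication
  A <- affine_transform(L = matrix(c(1.2, 0.1, -0.2, 0.9), 2, 2), T = c(10, -5))
  out2 <- apply_map_to_points(A, NULL, ps)
  direct <- sweep(ps$coords %*% t(A$L), 2, A$T, "+")
  expect_lt(max(abs(out2$coords - direct)), 1e-12)
  expect_identical(out2$features, ps$features)
  expect_identical(out2$labels, ps$labels)

  # forward then backward flow returns within one velocity-grid pixel
  vf <- smooth_test_velocity(test_axes_2d(), max_v = 100)
  fwd <- apply_map_to_points(NULL, integrate_velocity(vf, "forward"), ps)
  back <- apply_map_to_points(NULL, integrate_velocity(vf, "backward"), fwd)
  expect_lt(max(sqrt(rowSums((back$coords - ps$coords)^2))), 50)
})

test_that("resample_image implements the group action", {
  ps <- tiny_tissue(400, seed = 5)
  src <- rasterize(ps, dx = 50)

  # identity transform reproduces the source exactly on its own grid
  out <- resample_image(src, NULL, NULL, src$axes)
  expect_equal(out$values, src$values, tolerance = 1e-12)

  # integer-pixel translation shifts the array on the overlap
  A <- affine_transform(T = c(100, 0)) # +2 pixels in x
  sh <- resample_image(src, A, NULL, src$axes, fill = 0)
  nx <- length(src$axes$x)
  expect_equal(sh$values[, 3:nx, 1], src$values[, 1:(nx - 2), 1],
               tolerance = 1e-10)

  # warp then inverse-warp round trip stays within interpolation error
  vf <- smooth_test_velocity(diffeost:::pad_axes(src$axes, 2), max_v = 80,
                             seed = 8)
  phib <- integrate_velocity(vf, "backward")
  phif <- integrate_velocity(vf, "forward")
  warped <- resample_image(src, NULL, phib, src$axes, fill = 0)
  back <- resample_image(warped, NULL, phif, src$axes, fill = 0)
  # empirical linear-interpolation error bound for this image: one resample
  # at half-pixel shift
  half <- affine_transform(T = c(25, 25))
  ref <- resample_image(src, half, NULL, src$axes, fill = 0)
  ref2 <- resample_image(ref, diffeost:::affine_inverse(half), NULL, src$axes, fill = 0)
  bound <- max(abs(ref2$values - src$values))
  inner <- abs(src$values) > 0.1 * max(src$values)
  expect_lt(max(abs(back$values - src$values)[inner]), 2 * bound + 1e-12)
})

test_that("jacobian determinant of simple maps is exact", {
  axes <- test_axes_2d(500, 50)
  idm <- diffeost:::identity_map(axes)
  expect_equal(range(jacobian_determinant(idm)), c(1, 1))

  sc <- idm
  sc$positions <- sc$positions * 1.7
  expect_lt(max(abs(jacobian_determinant(sc) - 1.7^2)), 1e-10)

  # a generated smooth flow keeps positive determinant
  vf <- smooth_test_velocity(axes, max_v = 120, seed = 6)
  expect_gt(min(jacobian_determinant(integrate_velocity(vf, "forward"))), 0)
})

test_that("rasterizing mapped points commutes with resampling the raster", {
  ps <- tiny_tissue(500, seed = 10)
  A <- affine_transform(L = matrix(c(cos(0.2), sin(0.2), -sin(0.2), cos(0.2)),
                                   2, 2), T = c(80, -40)) # rigid: unit det
  moved <- apply_map_to_points(A, NULL, ps)
  rast_moved <- rasterize(moved, dx = 50, blur_std = 1.5)
  resamp <- resample_image(rasterize(ps, dx = 50, blur_std = 1.5), A, NULL,
                           rast_moved$axes, fill = 0)
  expect_lt(max(abs(rast_moved$values - resamp$values)),
            0.05 * max(rast_moved$values))
})
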