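test_that("operator symbol has the closed-form limits", {
  axes <- test_axes_2d(400, 50)
  Lh1 <- operator_symbol(axes, a = 500, p = 1)
  Lh2 <- operator_symbol(axes, a = 500, p = 2)
  expect_equal(Lh1[1, 1], 1) # zero frequency
  expect_equal(Lh2, Lh1^2, tolerance = 1e-12)
  expect_lt(max(abs(operator_symbol(axes, a = 1e-9, p = 2) - 1)), 1e-12)
})

test_that("regularization energy is the expected quadratic form", {
  axes <- test_axes_2d(400, 50)
  vf <- zero_velocity(axes, nt = 2, a = 500, p = 2)
  expect_identical(regularization_energy(vf), 0)

  # quadratic scaling
  vf$v[] <- rnorm(length(vf$v))
  e1 <- regularization_energy(vf, sigma_R = 1e3)
  vf2 <- vf; vf2$v <- 3 * vf$v
  expect_equal(regularization_energy(vf2, sigma_R = 1e3), 9 * e1,
               tolerance = 1e-10)

  # closed form on a single Fourier mode along one axis
  dims <- lengths(axes)
  k <- 2
  amp <- 4.2
  mode <- sin(2 * pi * k * (0:(dims[1] - 1)) / dims[1])
  vf3 <- zero_velocity(axes, nt = 1, a = 500, p = 2)
  vf3$v[, , 1, 1] <- matrix(mode, dims[1], dims[2])
  lhat_k <- (2 / 50^2) * (1 - cos(2 * pi * k / dims[1]))
  Lhat_k <- (1 + 500^2 * lhat_k)^2
  expected <- amp^2 * Lhat_k^2 * (dims[1] / 2) * dims[2] * 50^2 / 2
  vf3$v <- vf3$v * amp
  expect_equal(regularization_energy(vf3, sigma_R = 1), expected,
               tolerance = 1e-8)
})

test_that("smooth_gradient inverts L squared and damps high frequencies", {
  axes <- test_axes_2d(400, 50)
  # constant field unchanged (symbol is 1 at zero frequency)
  g0 <- array(3.7, c(lengths(axes), 2, 2))
  expect_equal(smooth_gradient(g0, axes, 500, 2), g0, tolerance = 1e-10)

  # applying L^2 then smoothing returns the original field
  set.seed(5)
  g <- array(rnorm(prod(lengths(axes)) * 2 * 2), c(lengths(axes), 2, 2))
  Lhat <- operator_symbol(axes, 500, 2)
  lg <- diffeost:::apply_multiplier(g, Lhat^2)
  expect_equal(smooth_gradient(lg, axes, 500, 2), g, tolerance = 1e-5)

  # the pure Nyquist mode (even grid) is attenuated exactly by the symbol
  axes_e <- lapply(1:2, function(j) seq(-400, 350, by = 50)) # 16 x 16
  dims <- lengths(axes_e)
  ny <- outer(rep_len(c(1, -1), dims[1]), rep_len(c(1, -1), dims[2]))
  ny <- array(ny, c(dims, 1, 1))
  out <- smooth_gradient(ny, axes_e, 500, 2)
  Lhat_e <- operator_symbol(axes_e, 500, 2)
  expect_equal(sum(out^2), sum(ny^2) / max(Lhat_e)^4, tolerance = 1e-8)
})

test_that("contrast fit solves exact and weighted polynomial relations", {
  set.seed(6)
  x <- runif(500)
  # linear relation, uniform weights
  y <- 2 * x + 1
  th <- fit_contrast(x, y, NULL, degree = 1)
  expect_equal(as.vector(th$coef), c(1, 2), tolerance = 1e-8)

  # identity under cubic fit
  th3 <- fit_contrast(x, matrix(x), NULL, degree = 3)
  expect_lt(max(abs(predict_contrast(th3, x) - x)), 1e-8)

  # random weights match the direct weighted normal equations
  y2 <- cbind(0.3 - 1.2 * x + 0.5 * x^2 + rnorm(500, sd = 0.05))
  w <- runif(500)
  th2 <- fit_contrast(x, y2, w, degree = 2)
  V <- cbind(1, x, x^2)
  oracle <- solve(t(V) %*% (w * V), t(V) %*% (w * y2))
  expect_equal(as.vector(th2$coef), as.vector(oracle), tolerance = 1e-8)

  # constant source falls back to the weighted mean
  expect_warning(thc <- fit_contrast(rep(0.5, 100), matrix(seq_len(100)),
                                     NULL, 2), "rank-deficient")
  expect_equal(thc$coef[1, 1], mean(seq_len(100)))
  expect_true(all(thc$coef[-1, ] == 0))
})

test_that("mixture EM reproduces hand-computed posteriors", {
  ew <- energy_weights(sigma_M = 0.2, sigma_B = 0.3, sigma_A = 0.4)
  # two pixels, one channel; fixed means, no M-step adaptation of the check
  pred <- matrix(c(0.8, 0.1))
  tgt <- matrix(c(0.75, 0.55))
  muB <- 0; muA <- 1
  W <- em_update_weights(pred, tgt, ew, mu_B = muB, mu_A = muA,
                         update_means = FALSE)
  for (px in 1:2) {
    dens <- c(dnorm(tgt[px], pred[px], 0.2),
              dnorm(tgt[px], muB, 0.3),
              dnorm(tgt[px], muA, 0.4)) / 3
    expect_lt(max(abs(W$posteriors[px, ] - dens / sum(dens))), 1e-12)
  }
  expect_lt(max(abs(rowSums(W$posteriors) - 1)), 1e-12)

  # target equal to prediction with distant means -> matching dominates
  W2 <- em_update_weights(matrix(0.5), matrix(0.5),
                          energy_weights(sigma_M = 0.05),
                          mu_B = -10, mu_A = 15, update_means = FALSE)
  expect_gt(W2$posteriors[1, 1], 0.99)

  # simplex property on random data, including M-step updates
  set.seed(7)
  W3 <- em_update_weights(matrix(runif(400)), matrix(runif(400)),
                          energy_weights(sigma_M = 0.1, sigma_B = 0.2,
                                         sigma_A = 0.2))
  expect_lt(max(abs(rowSums(W3$posteriors) - 1)), 1e-12)
  expect_true(all(W3$posteriors >= 0 & W3$posteriors <= 1))
  expect_equal(sum(W3$priors), 1, tolerance = 1e-12)
})

test_that("matching energy matches a brute-force SSD oracle", {
  set.seed(8)
  axes <- list(1:7 * 10, 1:9 * 10)
  pred <- raster_image(array(runif(63 * 2), c(7, 9, 2)), axes)
  tgt <- raster_image(array(runif(63 * 2), c(7, 9, 2)), axes)
  expect_identical(matching_energy(tgt, tgt), 0)
  expect_identical(matching_energy(pred, tgt, W = rep(0, 63)), 0)

  sigma_M <- 0.7
  got <- matching_energy(pred, tgt, NULL, sigma_M)
  oracle <- 0
  for (i in 1:7) for (j in 1:9) for (ch in 1:2)
    oracle <- oracle + (pred$values[i, j, ch] - tgt$values[i, j, ch])^2
  oracle <- oracle * 100 / (2 * sigma_M^2)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("landmark energy equals the closed-form penalty", {
  lm0 <- landmark_set(rbind(c(10, 20), c(-5, 3)), rbind(c(10, 20), c(-5, 3)))
  expect_identical(landmark_energy(NULL, NULL, lm0, 1), 0)

  # one pair offset by (3, 4) at sigma_P = 1: 25 / 2 = 12.5
  lm1 <- landmark_set(rbind(c(0, 0)), rbind(c(3, 4)))
  expect_equal(landmark_energy(NULL, NULL, lm1, sigma_P = 1), 12.5)

  # affine applied before comparison
  A <- affine_transform(T = c(3, 4))
  expect_equal(landmark_energy(A, NULL, lm1, sigma_P = 1), 0)
})
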