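#' Energy weights of the alignment objective
#'
#' Every sigma enters the objective as `1/(2*sigma^2)` (and, for the mixture
#' components, as the standard deviation of a Gaussian density): `sigma_M`
#' scales the image-matching term, `sigma_R` the velocity regularization,
#' `sigma_P` the landmark penalty, and `sigma_B`/`sigma_A` are the standard
#' deviations of the background and artifact mixture components.
#'
#' @param sigma_M,sigma_R,sigma_P,sigma_A,sigma_B Positive scalars.
#' @return Object of class `energy_weights`.
#' @export
energy_weights <- function(sigma_M = 1.0, sigma_R = 5e5, sigma_P = 2e1,
                           sigma_A = 5, sigma_B = 2) {
  w <- list(sigma_M = sigma_M, sigma_R = sigma_R, sigma_P = sigma_P,
            sigma_A = sigma_A, sigma_B = sigma_B)
  if (any(unlist(w) <= 0)) stop("all sigma values must be positive")
  structure(w, class = "energy_weights")
}

#' Spectral multiplier of the regularizing operator
#'
#' Fourier symbol of `L = (id - a^2 Laplacian)^p` on a uniform grid:
#' `Lhat(k) = (1 + a^2 * lhat(k))^p` with the discrete Laplacian symbol
#' `lhat(k) = sum_i (2/dx_i^2) (1 - cos(2 pi k_i / n_i))`. Used for
#' Fourier-domain filtering in the regularization energy and the natural
#' gradient.
#'
#' @param axes Grid axes (list of uniformly spaced coordinate vectors).
#' @param a Smoothness scale (micrometres).
#' @param p Power of the Laplacian.
#' @return Numeric array over the grid.
#' @export
operator_symbol <- function(axes, a, p) {
  stopifnot(a > 0, p >= 1)
  dims <- lengths(axes)
  (1 + a^2 * laplacian_symbol(dims, axis_spacing(axes)))^p
}

#' Sobolev regularization energy of a velocity field
#'
#' `R(v) = 1/(2 sigma_R^2) * (1/nt) * sum_t sum_x ||(L v_t)(x)||^2 * dx^d`
#' with `L = (id - a^2 Laplacian)^p` applied per component through its
#' Fourier symbol. A positive-definite quadratic form in `v` that penalizes
#' rough (high-frequency) velocity fields.
#'
#' @param vf A [velocity_field()].
#' @param sigma_R Regularization weight (standard-deviation convention).
#' @return Scalar energy.
#' @export
regularization_energy <- function(vf, sigma_R = 5e5) {
  Lhat <- operator_symbol(vf$axes, vf$a, vf$p)
  Lv <- apply_multiplier(vf$v, Lhat)
  sum(Lv^2) * prod(vf$dx) / (2 * sigma_R^2 * vf$nt)
}

#' Smooth a raw gradient into a natural gradient
#'
#' Derivatives of the objective with respect to `v` are covectors; descent in
#' the Sobolev metric multiplies their spectrum by `Lhat^{-2}` (the kernel
#' `K = (L' L)^{-1}`), suppressing high-frequency components so each step
#' stays in the space of smooth fields.
#'
#' @param grad Array shaped like a velocity field's samples (grid dims first).
#' @param axes Grid axes.
#' @param a,p Operator parameters as in [operator_symbol()].
#' @return Array of the same shape.
#' @export
smooth_gradient <- function(grad, axes, a, p) {
  Lhat <- operator_symbol(axes, a, p)
  apply_multiplier(grad, Lhat^(-2))
}

as_value_matrix <- function(x) {
  if (inherits(x, "raster_image")) {
    d <- length(x$axes)
    matrix(x$values, prod(grid_dims(x)), dim(x$values)[d + 1L])
  } else if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

#' Fit the polynomial contrast transform
#'
#' Weighted least-squares fit, per target channel, of a degree-`degree`
#' polynomial in the (single-channel) source intensity to the target
#' intensity, weighted by the matching posterior. Absorbs intensity
#' differences between modalities (cell-density rasters vs histology) so the
#' matching term compares comparable quantities.
#'
#' @param source A [raster_image()] (single channel), or a numeric vector of
#'   source intensities.
#' @param target A [raster_image()] or matrix of target intensities on the
#'   same grid.
#' @param W Matching weights: a `mixture_weights` object, a numeric vector,
#'   or NULL for uniform weights.
#' @param degree Polynomial degree (default 3).
#' @return Object of class `contrast_model` with `coef` (a `(degree+1) x
#'   n_channels` matrix, intercept first) and `degree`.
#' @export
fit_contrast <- function(source, target, W = NULL, degree = 3) {
  stopifnot(degree >= 0)
  x <- as_value_matrix(source)
  if (ncol(x) != 1L) stop("contrast fit requires a single-channel source")
  x <- as.vector(x)
  y <- as_value_matrix(target)
  w <- contrast_weights(W, length(x))
  V <- stats::poly(x, degree = max(degree, 1L), raw = TRUE, simple = TRUE)
  V <- cbind(1, V)[, seq_len(degree + 1L), drop = FALSE]
  sw <- sqrt(w)
  qx <- qr(sw * V)
  if (qx$rank < ncol(V)) {
    warning("rank-deficient contrast design (near-constant source); falling back to weighted mean")
    mu <- colSums(w * y) / sum(w)
    coef <- rbind(mu, matrix(0, degree, ncol(y)))
  } else {
    coef <- qr.coef(qx, sw * y)
  }
  dimnames(coef) <- NULL
  structure(list(coef = coef, degree = degree), class = "contrast_model")
}

contrast_weights <- function(W, n) {
  if (is.null(W)) return(rep(1, n))
  if (inherits(W, "mixture_weights")) return(W$posteriors[, 1L])
  as.numeric(W)
}

#' Evaluate a contrast model
#' @param model A `contrast_model`.
#' @param x Numeric vector of source intensities.
#' @return Matrix of predicted target intensities (one column per channel).
#' @export
predict_contrast <- function(model, x) {
  deg <- model$degree
  V <- outer(as.vector(x), 0:deg, `^`)
  V %*% model$coef
}

# Derivative of the contrast polynomial w.r.t. the source intensity.
deriv_contrast <- function(model, x) {
  deg <- model$degree
  if (deg == 0L) return(matrix(0, length(x), ncol(model$coef)))
  V <- outer(as.vector(x), 0:(deg - 1L), `^`)
  V %*% (model$coef[-1L, , drop = FALSE] * (1:deg))
}

#' EM update of the robust matching mixture
#'
#' Models each target pixel intensity as drawn from one of three isotropic
#' Gaussians: the matching component centered on the predicted (transformed,
#' contrast-adjusted) source intensity with sd `sigma_M`, a background
#' component centered on `mu_B` with sd `sigma_B`, and an artifact component
#' centered on `mu_A` with sd `sigma_A`. The E-step computes per-pixel Bayes
#' posteriors; the M-step updates the priors to the mean posteriors and (when
#' not fixed by the user) `mu_B`/`mu_A` to posterior-weighted target means.
#' The mixture is evaluated on the target only, so missing tissue and
#' artifacts in the target are explained away rather than dragging the map.
#'
#' @param pred Predicted target intensities ([raster_image()] or matrix).
#' @param target Observed target ([raster_image()] or matrix, same grid).
#' @param ew An [energy_weights()].
#' @param mu_B,mu_A Per-channel means; the strings `"black"`/`"white"` map to
#'   0/1 per channel; NULL starts at black/white and lets the M-step adapt.
#' @param priors Length-3 simplex vector (matching, background, artifact).
#' @param update_means Logical: apply the M-step to `mu_B`/`mu_A`?
#' @return Object of class `mixture_weights`: `posteriors` (n x 3 matrix in
#'   component order matching/background/artifact, rows summing to 1),
#'   `mu_B`, `mu_A`, `priors`, and `dims` when the inputs were images.
#' @export
em_update_weights <- function(pred, target, ew = energy_weights(),
                              mu_B = NULL, mu_A = NULL,
                              priors = rep(1, 3) / 3,
                              update_means = TRUE) {
  dims <- if (inherits(target, "raster_image")) grid_dims(target) else NULL
  y <- as_value_matrix(target)
  mu_M <- as_value_matrix(pred)
  nc <- ncol(y)
  if (ncol(mu_M) != nc) stop("pred and target must have matching channels")
  mu_B <- resolve_color(mu_B, nc, default = 0)
  mu_A <- resolve_color(mu_A, nc, default = 1)
  stopifnot(length(priors) == 3L, all(priors >= 0))
  priors <- priors / sum(priors)

  ll <- cbind(
    gauss_loglik(y, mu_M, ew$sigma_M),
    gauss_loglik(y, matrix(mu_B, nrow(y), nc, byrow = TRUE), ew$sigma_B),
    gauss_loglik(y, matrix(mu_A, nrow(y), nc, byrow = TRUE), ew$sigma_A)
  )
  lp <- sweep(ll, 2L, log(priors), "+")
  mx <- pmax(lp[, 1], lp[, 2], lp[, 3])
  bad <- !is.finite(mx)
  mx[bad] <- 0
  post <- exp(lp - mx)
  post[bad, ] <- 1
  post <- post / rowSums(post)

  new_priors <- colMeans(post)
  if (update_means) {
    sB <- sum(post[, 2])
    sA <- sum(post[, 3])
    if (sB > 0) mu_B <- colSums(post[, 2] * y) / sB
    if (sA > 0) mu_A <- colSums(post[, 3] * y) / sA
  }
  structure(list(posteriors = post, mu_B = mu_B, mu_A = mu_A,
                 priors = new_priors, dims = dims),
            class = "mixture_weights")
}

resolve_color <- function(mu, nc, default) {
  if (is.null(mu)) return(rep(default, nc))
  if (identical(mu, "black")) return(rep(0, nc))
  if (identical(mu, "white")) return(rep(1, nc))
  rep_len(as.numeric(mu), nc)
}

# Row-wise isotropic Gaussian log-likelihood across channels.
gauss_loglik <- function(y, mu, sigma) {
  nc <- ncol(y)
  -rowSums((y - mu)^2) / (2 * sigma^2) - nc * log(sigma * sqrt(2 * pi))
}

#' Weighted image-matching energy
#'
#' `M = 1/(2 sigma_M^2) * sum_x W_match(x) ||pred(x) - target(x)||^2 * dx^d`.
#'
#' @param pred,target Images or matrices on the same grid.
#' @param W `mixture_weights`, numeric vector of matching weights, or NULL
#'   for uniform.
#' @param sigma_M Matching weight.
#' @param pixel_volume Pixel volume `dx^d` (taken from `target` when it is a
#'   [raster_image()]).
#' @return Scalar energy.
#' @export
matching_energy <- function(pred, target, W = NULL, sigma_M = 1,
                            pixel_volume = NULL) {
  if (is.null(pixel_volume)) {
    if (!inherits(target, "raster_image"))
      stop("pixel_volume is required when target is not a raster_image")
    pixel_volume <- prod(target$dx)
  }
  y <- as_value_matrix(target)
  pr <- as_value_matrix(pred)
  w <- contrast_weights(W, nrow(y))
  sum(w * rowSums((pr - y)^2)) * pixel_volume / (2 * sigma_M^2)
}

#' Landmark penalty energy
#'
#' `1/(2 sigma_P^2) * sum_i || A phi1(s_i) - t_i ||^2` where `phi1` is the
#' forward flow of the velocity field (identity when `vf` is NULL).
#'
#' @param A An [affine_transform()] or NULL.
#' @param vf A [velocity_field()] or NULL.
#' @param lm A [landmark_set()].
#' @param sigma_P Landmark weight.
#' @return Scalar energy.
#' @export
landmark_energy <- function(A, vf, lm, sigma_P = 2e1) {
  s <- lm$source_pts
  if (!is.null(vf)) {
    fl <- flow_points(vf, pts_to_axis(s), "forward")
    s <- axis_to_pts(fl$final)
  }
  if (!is.null(A)) s <- apply_affine(A, s)
  sum((s - lm$target_pts)^2) / (2 * sigma_P^2)
}
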