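#' Solver configuration
#'
#' Collects every tunable of the alignment solve with its default. `dx` is the
#' rasterization width (micrometres); the `sigma_*` values weight objective
#' terms as in [energy_weights()]; `a` and `p` parameterize the smoothing
#' operator; `niter` is the number of gradient-descent epochs; `diffeo_start`
#' is the epoch (0-based) at which the velocity field starts updating
#' (coarse-to-fine: earlier epochs update the affine only); `nt` is the number
#' of timesteps when integrating the velocity field; `epL`, `epT`, `epV` are
#' the gradient-descent step sizes for the linear part, translation, and
#' velocity field. `pointsI`/`pointsJ` are optional source/target landmark
#' matrices; `muB`/`muA` are mixture means (numeric per channel, or
#' `"black"`/`"white"`; when given they are held fixed, when NULL they start
#' at black/white and are re-estimated every epoch). `L0`/`T0` or `A0`
#' (exclusive) give the initial affine guess.
#'
#' @param dx,sigma_M,sigma_R,sigma_P,sigma_A,sigma_B,a,p,niter,diffeo_start,nt,epL,epT,epV
#'   Numeric solver parameters (see description).
#' @param pointsI,pointsJ Optional m x d landmark matrices (source, target).
#' @param muB,muA Mixture component means (see [em_update_weights()]).
#' @param L0,T0,A0 Initial affine guess: linear part + translation, or the
#'   full homogeneous matrix, but not both.
#' @param contrast_degree Polynomial degree of the contrast transform.
#' @param seed Optional integer recorded for provenance (the solver itself is
#'   deterministic; the seed governs synthetic inputs only).
#' @param verbose Print the objective every `verbose` epochs (0 = silent).
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(dx = 30, sigma_M = 1.0, sigma_R = 5e5,
                          sigma_P = 2e1, sigma_A = 5, sigma_B = 2,
                          a = 500, p = 2, niter = 5000, diffeo_start = 0,
                          nt = 3, epL = 2e-8, epT = 2e-1, epV = 2e3,
                          pointsI = NULL, pointsJ = NULL,
                          muB = NULL, muA = NULL,
                          L0 = NULL, T0 = NULL, A0 = NULL,
                          contrast_degree = 3, seed = NULL, verbose = 0) {
  if (!is.null(A0) && (!is.null(L0) || !is.null(T0)))
    stop("either L0 and T0 can be specified, or A0, but not both")
  cfg <- list(dx = dx, sigma_M = sigma_M, sigma_R = sigma_R, sigma_P = sigma_P,
              sigma_A = sigma_A, sigma_B = sigma_B, a = a, p = p,
              niter = as.integer(niter), diffeo_start = as.integer(diffeo_start),
              nt = as.integer(nt), epL = epL, epT = epT, epV = epV,
              pointsI = pointsI, pointsJ = pointsJ, muB = muB, muA = muA,
              L0 = L0, T0 = T0, A0 = A0,
              contrast_degree = as.integer(contrast_degree),
              seed = seed, verbose = verbose)
  stopifnot(cfg$dx > 0, cfg$a > 0, cfg$p >= 1, cfg$niter >= 1, cfg$nt >= 1,
            cfg$diffeo_start >= 0)
  structure(cfg, class = "solver_config")
}

# Pad each axis of a grid by `pad` pixels on both sides.
pad_axes <- function(axes, pad = 2L) {
  lapply(axes, function(ax) {
    dx <- if (length(ax) > 1L) ax[2L] - ax[1L] else 1
    c(ax[1L] - (pad:1) * dx, ax, ax[length(ax)] + (1:pad) * dx)
  })
}

# Intensity-weighted centroid of an image, axis order.
image_centroid <- function(img) {
  d <- length(img$axes)
  w <- rowSums(matrix(img$values, prod(grid_dims(img)), n_channels(img)))
  w <- pmax(w, 0)
  X <- matrix(grid_coords(img$axes), prod(grid_dims(img)), d)
  colSums(X * w) / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One forward evaluation of the geometric pipeline: backward flow stack,
# affine-inverse sampling of the target grid, interpolation of the source.
# Everything the contrast fit, the EM step and the adjoint need; derivatives
# of the interpolants are kept when with_grads = TRUE.
align_forward <- function(A_ax, vf, src_vals, src_axes, tgt_pts_ax,
                          with_grads = TRUE) {
  nt <- vf$nt
  st <- flow_map_stack(vf, "backward")
  B <- affine_inverse(A_ax)
  z <- apply_affine(B, tgt_pts_ax)
  disp_nt <- st$maps[[nt + 1L]] - st$X
  gq_i <- grid_interp(disp_nt, vf$axes, z, deriv = with_grads)
  q <- z + gq_i$values
  gI <- grid_interp(src_vals, src_axes, q, deriv = with_grads)
  list(st = st, B = B, z = z, gq_i = gq_i, q = q, gI = gI,
       pred_raw = as.vector(gI$values))
}

# Energies and exact gradients of the composed objective at fixed mixture
# weights and contrast model: the hand-derived adjoint of the discrete
# forward computation (semi-Lagrangian flow -> affine-inverse sampling ->
# multilinear image interpolation -> polynomial contrast -> weighted SSD),
# plus the quadratic regularizer and landmark penalty. A_ax is an axis-order
# affine; tgt_pts_ax are target sample positions embedded in
# source-dimensional space; lm_ax holds axis-order landmarks.
energy_and_grads <- function(A_ax, vf, src_vals, src_axes, tgt_pts_ax, tgt_y,
                             w_match, theta, ew, pixvol, lm_ax = NULL,
                             with_grads = TRUE, fw = NULL, need_gv = TRUE) {
  d <- length(vf$axes)
  dims_v <- lengths(vf$axes)
  npix_v <- prod(dims_v)
  nt <- vf$nt
  dt <- 1 / nt
  m <- nrow(tgt_pts_ax)

  if (is.null(fw))
    fw <- align_forward(A_ax, vf, src_vals, src_axes, tgt_pts_ax, with_grads)
  pred_raw <- fw$pred_raw
  pred <- predict_contrast(theta, pred_raw)
  resid <- pred - tgt_y

  E_M <- sum(w_match * rowSums(resid^2)) * pixvol / (2 * ew$sigma_M^2)
  E_R <- regularization_energy(vf, ew$sigma_R)

  E_P <- 0
  lm_path <- NULL
  lm_res <- NULL
  if (!is.null(lm_ax)) {
    fl <- flow_points(vf, lm_ax$s, "forward", store = TRUE)
    lm_res <- apply_affine(A_ax, fl$final) - lm_ax$t
    E_P <- sum(lm_res^2) / (2 * ew$sigma_P^2)
    lm_path <- fl
  }

  out <- list(E_M = E_M, E_R = E_R, E_P = E_P, total = E_M + E_R + E_P,
              pred = pred, pred_raw = pred_raw,
              outside_source = fw$gI$outside)
  if (!with_grads) return(out)

  # --- matching-term adjoint ---
  gpred <- (pixvol / ew$sigma_M^2) * (w_match * resid)           # m x nc
  dpoly <- deriv_contrast(theta, pred_raw)                        # m x nc
  gpred_raw <- rowSums(gpred * dpoly)                             # m
  gq <- matrix(0, m, d)
  for (j in seq_len(d)) gq[, j] <- gpred_raw * fw$gI$deriv[, j, 1L]

  # through q = z + disp(z):  gz_j = gq_j + sum_i d(disp_i)/d(z_j) * gq_i
  gz <- gq
  for (j in seq_len(d))
    for (i in seq_len(d))
      gz[, j] <- gz[, j] + fw$gq_i$deriv[, j, i] * gq[, i]

  # affine gradient via B = A^{-1}:  dE/dA = -B' (dE/dB) B'
  gB <- matrix(0, d + 1L, d + 1L)
  gB[seq_len(d), seq_len(d)] <- crossprod(gz, tgt_pts_ax)
  gB[seq_len(d), d + 1L] <- colSums(gz)
  Bm <- fw$B$matrix
  gA <- -t(Bm) %*% gB %*% t(Bm)

  # velocity adjoint through the semi-Lagrangian recursion
  st <- fw$st
  gv <- array(0, c(npix_v, d, nt))
  if (need_gv) {
  G <- matrix(grid_scatter(gq, dims_v, vf$axes, fw$z), npix_v, d)
  for (k in nt:1) {
    t_k <- st$tseq[k]
    Xs <- st$samples[[k]]
    disp_prev <- st$maps[[k]] - st$X
    gi <- grid_interp(disp_prev, vf$axes, Xs, deriv = TRUE)
    gXs <- G
    for (j in seq_len(d))
      for (i in seq_len(d))
        gXs[, j] <- gXs[, j] + gi$deriv[, j, i] * G[, i]
    gv[, , t_k] <- gv[, , t_k] - dt * gXs
    G <- matrix(grid_scatter(G, dims_v, vf$axes, Xs), npix_v, d)
  }
  }

  # landmark adjoint (forward point flow)
  if (!is.null(lm_ax)) {
    gA[seq_len(d), seq_len(d)] <- gA[seq_len(d), seq_len(d)] +
      crossprod(lm_res, lm_path$final) / ew$sigma_P^2
    gA[seq_len(d), d + 1L] <- gA[seq_len(d), d + 1L] +
      colSums(lm_res) / ew$sigma_P^2
    lam <- (lm_res %*% A_ax$L) / ew$sigma_P^2
    if (need_gv) for (k in nt:1) {
      t_k <- lm_path$tseq[k]
      xk <- lm_path$path[[k]]
      vt <- array(vf$v[slice_time(vf, t_k)], c(dims_v, d))
      gi <- grid_interp(vt, vf$axes, xk, deriv = TRUE)
      gv[, , t_k] <- gv[, , t_k] +
        matrix(grid_scatter(dt * lam, dims_v, vf$axes, xk), npix_v, d)
      lam_new <- lam
      for (j in seq_len(d))
        for (i in seq_len(d))
          lam_new[, j] <- lam_new[, j] + dt * gi$deriv[, j, i] * lam[, i]
      lam <- lam_new
    }
  }

  # regularization gradient: dR/dv = dx^d/(sigma_R^2 nt) * L'L v
  gv <- array(gv, c(dims_v, d, nt))
  if (need_gv) {
    Lhat <- operator_symbol(vf$axes, vf$a, vf$p)
    gv <- gv +
      (prod(vf$dx) / (ew$sigma_R^2 * nt)) * apply_multiplier(vf$v, Lhat^2)
  }

  out$gA <- gA
  out$gv <- gv
  out
}

# Shared gradient-descent loop for 2D->2D and 3D->2D alignment.
lddmm_loop <- function(src, tgt, cfg, lm, tgt_pts_ax, embed_3d = FALSE) {
  d <- length(src$axes)
  if (n_channels(src) != 1L)
    stop("the source must be a single-channel (density) image")
  ew <- energy_weights(cfg$sigma_M, cfg$sigma_R, cfg$sigma_P,
                       cfg$sigma_A, cfg$sigma_B)
  nc <- n_channels(tgt)
  tgt_y <- as_value_matrix(tgt)
  pixvol <- prod(tgt$dx)
  m <- nrow(tgt_y)

  if (is.null(lm) && !is.null(cfg$pointsI))
    lm <- landmark_set(cfg$pointsI, cfg$pointsJ)
  lm_ax <- NULL
  if (!is.null(lm))
    lm_ax <- list(s = pts_to_axis(lm$source_pts), t = pts_to_axis(lm$target_pts))

  # initial affine (point order), then converted to axis order
  A <- if (!is.null(lm)) {
    fit_affine_landmarks(lm)
  } else if (!is.null(cfg$A0)) {
    affine_transform(matrix = cfg$A0)
  } else if (!is.null(cfg$L0) || !is.null(cfg$T0)) {
    affine_transform(L = if (is.null(cfg$L0)) diag(d) else cfg$L0,
                     T = if (is.null(cfg$T0)) rep(0, d) else cfg$T0)
  } else {
    cs <- image_centroid(src)
    ct_ax <- if (embed_3d) c(0, image_centroid(tgt)) else image_centroid(tgt)
    affine_transform(L = diag(d), T = axis_to_pts(rbind(ct_ax - cs))[1, ])
  }
  A_ax <- affine_reverse_order(A)

  v_axes <- pad_axes(src$axes, 2L)
  vf <- zero_velocity(v_axes, nt = cfg$nt, a = cfg$a, p = cfg$p)

  fix_B <- !is.null(cfg$muB)
  fix_A <- !is.null(cfg$muA)
  mu_B <- resolve_color(cfg$muB, nc, default = 0)
  mu_A <- resolve_color(cfg$muA, nc, default = 1)
  priors <- rep(1, 3) / 3
  w_match <- rep(1, m)
  theta <- NULL
  Wm <- NULL

  # Warm-start the contrast transform and mixture with a few EM sweeps at the
  # initial transform so epoch-1 energies are measured under stabilized
  # weights and the recorded loss history is comparable across epochs.
  fw0 <- align_forward(A_ax, vf, src$values, src$axes, tgt_pts_ax,
                       with_grads = FALSE)
  if (all(fw0$gI$outside))
    stop("the target plane maps entirely outside the source at initialization; provide a better initial translation (T0)")
  for (sweep_i in 1:5) {
    theta <- fit_contrast(fw0$pred_raw, tgt_y, w_match, cfg$contrast_degree)
    Wm <- em_update_weights(predict_contrast(theta, fw0$pred_raw), tgt_y, ew,
                            mu_B = mu_B, mu_A = mu_A, priors = priors,
                            update_means = TRUE)
    if (!fix_B) mu_B <- Wm$mu_B
    if (!fix_A) mu_A <- Wm$mu_A
    priors <- Wm$priors
    w_match <- Wm$posteriors[, 1L]
  }

  loss <- matrix(NA_real_, cfg$niter, 4,
                 dimnames = list(NULL, c("R", "M", "P", "total")))
  for (epoch in seq_len(cfg$niter)) {
    fw <- align_forward(A_ax, vf, src$values, src$axes, tgt_pts_ax,
                        with_grads = TRUE)
    if (epoch == 1L && all(fw$gI$outside))
      stop("the target plane maps entirely outside the source at initialization; provide a better initial translation (T0)")
    theta <- fit_contrast(fw$pred_raw, tgt_y, w_match, cfg$contrast_degree)
    pred <- predict_contrast(theta, fw$pred_raw)
    Wm <- em_update_weights(pred, tgt_y, ew, mu_B = mu_B, mu_A = mu_A,
                            priors = priors, update_means = TRUE)
    if (!fix_B) mu_B <- Wm$mu_B else Wm$mu_B <- mu_B
    if (!fix_A) mu_A <- Wm$mu_A else Wm$mu_A <- mu_A
    priors <- Wm$priors
    w_match <- Wm$posteriors[, 1L]

    update_v <- (epoch - 1L) >= cfg$diffeo_start
    eg <- energy_and_grads(A_ax, vf, src$values, src$axes, tgt_pts_ax, tgt_y,
                           w_match, theta, ew, pixvol, lm_ax = lm_ax, fw = fw,
                           need_gv = update_v)
    loss[epoch, ] <- c(eg$E_R, eg$E_M, eg$E_P, eg$total)
    if (!is.finite(eg$total))
      stop(sprintf("objective became non-finite at epoch %d; reduce step sizes (epL/epT/epV)", epoch))
    if (cfg$verbose > 0 && epoch %% cfg$verbose == 0)
      message(sprintf("epoch %d: R=%.4g M=%.4g P=%.4g total=%.4g",
                      epoch, eg$E_R, eg$E_M, eg$E_P, eg$total))

    A_ax <- affine_transform(
      L = A_ax$L - cfg$epL * eg$gA[seq_len(d), seq_len(d)],
      T = A_ax$T - cfg$epT * eg$gA[seq_len(d), d + 1L])
    if (update_v)
      vf$v <- vf$v - cfg$epV * smooth_gradient(eg$gv, vf$axes, vf$a, vf$p)
  }

  Wm$dims <- lengths(tgt$axes)
  structure(list(
    A = affine_reverse_order(A_ax),
    v = vf,
    loss_history = as.data.frame(cbind(epoch = seq_len(cfg$niter), loss)),
    W = Wm,
    theta = theta,
    source_axes = src$axes,
    target_axes = tgt$axes,
    embed_3d = embed_3d,
    config = cfg
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  n <- nrow(x$loss_history)
  cat(sprintf("alignment_result: %dD source, %d epochs, objective %.5g -> %.5g\n",
              length(x$v$axes), n, x$loss_history$total[1L],
              x$loss_history$total[n]))
  invisible(x)
}

#' Solve a 2D diffeomorphic alignment
#'
#' Steepest gradient descent on the affine transform and time-varying
#' velocity field minimizing `R(v) + M + landmark penalty`. Per epoch: the
#' backward flow is integrated and the source resampled onto the target grid;
#' the polynomial contrast transform is refit; the three-component Gaussian
#' mixture is EM-updated; the objective and its exact gradients are evaluated
#' (holding mixture weights and contrast fixed, the standard EM-in-the-loop
#' treatment); the linear part, translation and velocity field descend with
#' step sizes `epL`, `epT` and `epV` (the velocity gradient after natural-
#' gradient smoothing, and only from epoch `diffeo_start` on). The affine is
#' initialized from landmarks by least squares when given, else from
#' `L0`/`T0`/`A0`, else as a translation aligning image centroids.
#'
#' @param source,target Single-channel source [raster_image()] and (possibly
#'   multi-channel) target [raster_image()].
#' @param cfg A [solver_config()].
#' @param lm Optional [landmark_set()] (source/target, micrometres).
#' @return An `alignment_result`: `A` (point-order [affine_transform()]), `v`
#'   ([velocity_field()]), `loss_history` (data frame, one row per epoch with
#'   R/M/P/total), `W` (final `mixture_weights` on the target grid), `theta`
#'   (final contrast model), grid metadata and the config.
#' @export
run_lddmm <- function(source, target, cfg = solver_config(), lm = NULL) {
  stopifnot(length(source$axes) == 2L, length(target$axes) == 2L)
  tgt_pts_ax <- matrix(grid_coords(target$axes), prod(grid_dims(target)), 2L)
  lddmm_loop(source, target, cfg, lm, tgt_pts_ax, embed_3d = FALSE)
}

#' Solve a 3D-to-2D diffeomorphic alignment
#'
#' Aligns a 3D source volume (for example a reconstructed atlas intensity
#' volume) to a 2D target section. The target grid is embedded at the z = 0
#' plane of target space; a full 3D affine and 3D velocity field are solved so
#' the section can cut obliquely through the volume and deform out of plane.
#' The slice depth is absorbed into the z-translation of the affine.
#'
#' @param source_vol 3D single-channel [raster_image()].
#' @param target_img 2D [raster_image()].
#' @param cfg A [solver_config()]; `T0` (x, y, z) sets the initial
#'   translation, z picking the starting slice depth.
#' @return An `alignment_result` with a 3D affine and velocity field.
#' @export
run_lddmm_3d_to_2d <- function(source_vol, target_img, cfg = solver_config()) {
  stopifnot(length(source_vol$axes) == 3L, length(target_img$axes) == 2L)
  m <- prod(grid_dims(target_img))
  pts2 <- matrix(grid_coords(target_img$axes), m, 2L)
  tgt_pts_ax <- cbind(0, pts2) # (z = 0, y, x)
  lddmm_loop(source_vol, target_img, cfg, lm = NULL, tgt_pts_ax,
             embed_3d = TRUE)
}

#' Transform points through a solved alignment
#'
#' `direction = "forward"` maps source-space points into target space
#' (`A(phi1(x))`: Euler integration of the solved velocity field followed by
#' the affine); `"inverse"` maps target-space points back into source space
#' (`phi1^{-1}(A^{-1} x)`).
#'
#' @param result An `alignment_result`.
#' @param points A [point_set()] with the source (forward) or target
#'   (inverse) dimensionality; for 3D-to-2D results, 2D target points are
#'   embedded at z = 0 automatically in the inverse direction, and forward-
#'   mapped 3D points are returned as their in-plane (x, y) coordinates.
#' @param direction `"forward"` or `"inverse"`.
#' @return A [point_set()] of mapped coordinates.
#' @export
transform_points <- function(result, points,
                             direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  d <- length(result$v$axes)
  co <- points$coords
  if (direction == "forward") {
    if (ncol(co) != d) stop("points must match the source dimension")
    fl <- flow_points(result$v, pts_to_axis(co), "forward")
    out <- apply_affine(result$A, axis_to_pts(fl$final))
    if (result$embed_3d) out <- out[, c(1L, 2L), drop = FALSE]
  } else {
    if (result$embed_3d && ncol(co) == 2L) {
      B_ax <- affine_inverse(affine_reverse_order(result$A))
      ax <- apply_affine(B_ax, cbind(0, pts_to_axis(co)))
    } else {
      if (ncol(co) != d) stop("points must match the source dimension")
      ax <- pts_to_axis(apply_affine(affine_inverse(result$A), co))
    }
    fl <- flow_points(result$v, ax, "backward")
    out <- axis_to_pts(fl$final)
  }
  colnames(out) <- c("x", "y", "z")[seq_len(ncol(out))]
  point_set(out, features = points$features, labels = points$labels)
}

#' Matching-probability mask
#'
#' Thresholds the posterior probability of the matched mixture component:
#' a target pixel is considered reliably aligned tissue when its matching
#' posterior exceeds `threshold` (default 0.85). When `points` (source cells)
#' are supplied they are transformed into target space and flagged by
#' nearest-pixel lookup; points landing outside the target grid are flagged
#' non-matching.
#'
#' @param result An `alignment_result`.
#' @param threshold Posterior cutoff (default 0.85).
#' @param points Optional source [point_set()].
#' @return List with `mask` (logical array on the target grid), `threshold`,
#'   and, when `points` is given, `point_flags` (logical per point).
#' @export
matching_mask <- function(result, threshold = 0.85, points = NULL) {
  dims <- unname(lengths(result$target_axes))
  mask <- array(result$W$posteriors[, 1L] > threshold, dims)
  out <- list(mask = mask, threshold = threshold)
  if (!is.null(points)) {
    tp <- transform_points(result, points, "forward")
    nn <- nearest_pixel(result$target_axes, pts_to_axis(tp$coords))
    flags <- as.vector(mask)[nn$lin]
    flags[!nn$inside] <- FALSE
    out$point_flags <- flags
  }
  out
}

# Nearest-pixel linear index on a grid for axis-order query points.
nearest_pixel <- function(axes, pa) {
  d <- length(axes)
  dims <- lengths(axes)
  idx <- matrix(0L, nrow(pa), d)
  inside <- rep(TRUE, nrow(pa))
  for (j in seq_len(d)) {
    ax <- axes[[j]]
    dxj <- if (length(ax) > 1L) ax[2L] - ax[1L] else 1
    ij <- as.integer(round((pa[, j] - ax[1L]) / dxj)) + 1L
    inside <- inside & ij >= 1L & ij <= length(ax)
    idx[, j] <- pmin(pmax(ij, 1L), length(ax))
  }
  lin <- idx[, 1L]
  stride <- 1L
  for (j in seq_len(d - 1L)) {
    stride <- stride * dims[j]
    lin <- lin + (idx[, j + 1L] - 1L) * stride
  }
  list(lin = lin, inside = inside)
}

#' Annotation label volume
#'
#' @param labels 3D integer array of region ids (0 = background/outside).
#' @param axes List of 3 coordinate vectors (micrometres), (z, y, x) order.
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(labels, axes) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L || length(axes) != 3L)
    stop("labels must be a 3D array with 3 axes")
  if (!all(dim(labels) == lengths(axes)))
    stop("axis lengths must match the label grid")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  dim(labels) <- unname(dim(labels))
  check_axes(axes)
  names(axes) <- c("z", "y", "x")
  structure(list(labels = labels, axes = axes, dx = axis_spacing(axes)),
            class = "label_volume")
}

#' Lift atlas annotations over to cells
#'
#' Each 2D cell is embedded at z = 0 of target space, mapped back into the
#' source (atlas) volume through the solved 3D-to-2D alignment (inverse
#' affine followed by the backward flow), and annotated with the label of the
#' nearest voxel. Cells mapping outside the volume receive 0.
#'
#' @param result An `alignment_result` from [run_lddmm_3d_to_2d()].
#' @param labels A [label_volume()] on the source volume's coordinate system.
#' @param cells A 2D [point_set()] in target coordinates.
#' @return Integer vector of per-cell label ids.
#' @export
lift_over_labels <- function(result, labels, cells) {
  if (!result$embed_3d)
    stop("lift_over_labels requires a 3D-to-2D alignment result")
  if (point_dim(cells) != 2L) stop("cells must be a 2D point set")
  src <- transform_points(result, cells, "inverse")
  nn <- nearest_pixel(labels$axes, pts_to_axis(src$coords))
  out <- as.vector(labels$labels)[nn$lin]
  out[!nn$inside] <- 0L
  as.integer(out)
}
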