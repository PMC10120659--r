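#' Affine transform in homogeneous coordinates
#'
#' Represents a d-dimensional affine map acting on point coordinates in
#' (x, y\[, z\]) order: `p -> L p + T`.
#'
#' @param matrix Full (d+1) x (d+1) homogeneous matrix, exclusive with
#'   `L`/`T`.
#' @param L d x d linear part (default identity).
#' @param T length-d translation (default zero).
#' @param d Dimension, used when only defaults are wanted.
#' @return Object of class `affine_transform` with elements `matrix`, `L`,
#'   `T`.
#' @export
affine_transform <- function(matrix = NULL, L = NULL, T = NULL, d = 2L) {
  if (!is.null(matrix) && (!is.null(L) || !is.null(T)))
    stop("specify either the full matrix or L/T, not both")
  if (!is.null(matrix)) {
    matrix <- as.matrix(matrix)
    d <- nrow(matrix) - 1L
    L <- matrix[seq_len(d), seq_len(d), drop = FALSE]
    T <- matrix[seq_len(d), d + 1L]
  } else {
    if (!is.null(L)) d <- nrow(as.matrix(L))
    if (is.null(L)) L <- diag(d)
    if (is.null(T)) T <- rep(0, d)
    L <- as.matrix(L)
    matrix <- rbind(cbind(L, T), c(rep(0, d), 1))
  }
  if (any(abs(matrix[d + 1L, ] - c(rep(0, d), 1)) > 1e-12))
    stop("last row of a homogeneous affine matrix must be (0, ..., 0, 1)")
  if (abs(det(L)) < .Machine$double.eps)
    stop("affine linear part is singular")
  dimnames(matrix) <- NULL
  structure(list(matrix = matrix, L = unname(L), T = unname(as.numeric(T))),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  d <- length(x$T)
  cat(sprintf("affine_transform (%dD): det(L) = %.4g, T = (%s) um\n",
              d, det(x$L), paste(signif(x$T, 5), collapse = ", ")))
  invisible(x)
}

affine_identity <- function(d) affine_transform(d = d)

affine_inverse <- function(A) {
  Li <- solve(A$L)
  affine_transform(L = Li, T = -as.numeric(Li %*% A$T))
}

# Apply to point-order coordinates (m x d).
apply_affine <- function(A, pts) {
  sweep(pts %*% t(A$L), 2L, A$T, "+")
}

# Internal: convert an affine acting on (x,y[,z]) point coordinates to one
# acting on axis-order ((z,)y,x) coordinates (conjugation by the reversal
# permutation), and back.
affine_reverse_order <- function(A) {
  d <- length(A$T)
  perm <- rev(seq_len(d))
  affine_transform(L = A$L[perm, perm, drop = FALSE], T = A$T[perm])
}

#' Paired landmark coordinates
#'
#' @param source_pts,target_pts m x d matrices of matching positions
#'   (micrometres, (x, y\[, z\]) columns), paired by row.
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(source_pts, target_pts) {
  source_pts <- as.matrix(source_pts)
  target_pts <- as.matrix(target_pts)
  if (!all(dim(source_pts) == dim(target_pts)))
    stop("source and target landmarks must have matching dimensions")
  if (nrow(source_pts) < 1L) stop("at least one landmark pair is required")
  if (any(!is.finite(source_pts)) || any(!is.finite(target_pts)))
    stop("landmark coordinates must be finite")
  structure(list(source_pts = unname(source_pts),
                 target_pts = unname(target_pts)),
            class = "landmark_set")
}

#' Least-squares affine fit to paired landmarks
#'
#' Solves `argmin_A sum_i || A s_i - t_i ||^2` over all affine transforms,
#' the standard initialization (and supervised baseline) for registration.
#'
#' @param lm A [landmark_set()] with at least d + 1 non-degenerate pairs.
#' @return An [affine_transform()]; attribute `"rss"` carries the residual
#'   sum of squares and `"rmse"` the root-mean-square residual.
#' @export
fit_affine_landmarks <- function(lm) {
  s <- lm$source_pts
  t <- lm$target_pts
  d <- ncol(s)
  m <- nrow(s)
  if (m < d + 1L)
    stop(sprintf("need at least %d landmark pairs for a %dD affine fit", d + 1L, d))
  X <- cbind(s, 1)
  qx <- qr(X)
  if (qx$rank < d + 1L)
    stop("degenerate landmark configuration (collinear/coplanar source points); add more spread-out landmarks")
  M <- qr.coef(qx, t)
  A <- affine_transform(L = t(M[seq_len(d), , drop = FALSE]), T = M[d + 1L, ])
  res <- X %*% M - t
  attr(A, "rss") <- sum(res^2)
  attr(A, "rmse") <- sqrt(mean(rowSums(res^2)))
  A
}

#' Time-varying velocity field
#'
#' A smooth velocity field sampled at `nt` timesteps on its own uniform grid;
#' integrating it in time generates the diffeomorphic part of the alignment.
#'
#' @param v Array `c(grid dims, d, nt)` of velocity samples (micrometres per
#'   unit time), components in axis order ((z,) y, x).
#' @param axes Grid axes as in [raster_image()].
#' @param a Smoothness scale of the diffeomorphism (micrometres, default 500).
#' @param p Power of the Laplacian in the regularizing operator (default 2).
#' @return Object of class `velocity_field`.
#' @export
velocity_field <- function(v, axes, a = 500, p = 2) {
  d <- length(axes)
  v <- as.array(v)
  if (length(dim(v)) != d + 2L || dim(v)[d + 1L] != d)
    stop("v must be an array c(grid dims, d, nt)")
  if (!all(dim(v)[seq_len(d)] == lengths(axes)))
    stop("velocity grid shape must match axes")
  if (any(!is.finite(v))) stop("velocity values must be finite")
  dim(v) <- unname(dim(v))
  stopifnot(a > 0, p >= 1, dim(v)[d + 2L] >= 1L)
  check_axes(axes)
  structure(list(v = v, axes = axes, nt = dim(v)[d + 2L], a = a, p = p,
                 dx = axis_spacing(axes)),
            class = "velocity_field")
}

zero_velocity <- function(axes, nt = 3, a = 500, p = 2) {
  d <- length(axes)
  velocity_field(array(0, c(lengths(axes), d, nt)), axes, a = a, p = p)
}

# Grid coordinate array: c(dims, d), X[..., j] = axes[[j]] broadcast.
grid_coords <- function(axes) {
  dims <- unname(lengths(axes))
  d <- length(axes)
  X <- array(0, c(dims, d))
  tmp <- array(0, dims)
  for (j in seq_len(d)) {
    coordj <- array(axes[[j]][slice.index(tmp, j)], dims)
    X <- fill_component(X, j, coordj)
  }
  X
}

# Assign/extract component j (second-to-last dim of a c(dims, d) array).
fill_component <- function(X, j, val) {
  dims <- dim(X)
  d <- dims[length(dims)]
  npix <- prod(dims[-length(dims)])
  Xm <- matrix(X, npix, d)
  Xm[, j] <- as.vector(val)
  array(Xm, dims)
}

# Semi-Lagrangian integration of v: returns the list of partial maps
# psi_t (t = 0..nt) for direction "backward" (psi_nt = phi1^{-1}, the map
# used to resample images) or F_t for "forward" (F_0 = phi1, the map applied
# to source points). Intermediate maps are kept for the solver's adjoint.
flow_map_stack <- function(vf, direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  d <- length(vf$axes)
  dims <- lengths(vf$axes)
  nt <- vf$nt
  dt <- 1 / nt
  X <- grid_coords(vf$axes)
  npix <- prod(dims)
  Xpts <- matrix(X, npix, d)
  vmat <- array(vf$v, c(npix, d, nt))
  maps <- vector("list", nt + 1L)
  samples <- vector("list", nt)
  phi <- X
  maps[[1L]] <- phi
  tseq <- if (direction == "backward") seq_len(nt) else rev(seq_len(nt))
  sgn <- if (direction == "backward") -1 else 1
  for (k in seq_len(nt)) {
    t <- tseq[k]
    Xs <- Xpts + sgn * dt * vmat[, , t]
    disp <- array(as.vector(phi) - as.vector(X), c(dims, d))
    g <- grid_interp(disp, vf$axes, Xs)
    phi <- array(g$values + Xs, c(dims, d))
    maps[[k + 1L]] <- phi
    samples[[k]] <- Xs
  }
  list(maps = maps, samples = samples, tseq = tseq, X = X, direction = direction)
}

#' Integrate a velocity field into a diffeomorphism
#'
#' Semi-Lagrangian Euler integration with `nt` timesteps and linear
#' interpolation. `direction = "forward"` returns the time-1 flow map
#' (applied to source points); `"backward"` returns its inverse (used to
#' resample images), obtained by integrating the negated field in reversed
#' time order.
#'
#' @param vf A [velocity_field()].
#' @param direction `"forward"` or `"backward"`.
#' @return Object of class `diffeo_map`: `positions` (array `c(dims, d)` of
#'   mapped positions, axis-order components), `axes`, `direction`.
#' @export
integrate_velocity <- function(vf, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  st <- flow_map_stack(vf, direction)
  structure(list(positions = st$maps[[vf$nt + 1L]], axes = vf$axes,
                 direction = direction),
            class = "diffeo_map")
}

identity_map <- function(axes) {
  structure(list(positions = grid_coords(axes), axes = axes,
                 direction = "forward"),
            class = "diffeo_map")
}

# Evaluate a sampled map at axis-order query points (nearest-edge extension
# of the displacement outside the grid). Returns m x d positions.
eval_map <- function(phi, pts_ax) {
  d <- length(phi$axes)
  X <- grid_coords(phi$axes)
  disp <- phi$positions - X
  g <- grid_interp(disp, phi$axes, pts_ax)
  list(positions = g$values + pts_ax, outside = g$outside)
}

#' Apply an affine and a diffeomorphism to points
#'
#' Computes `A(phi(x))` per point: the diffeomorphic flow first, then the
#' affine, matching how the alignment map is composed. Features and labels
#' are carried through unchanged. Points falling outside the map's grid use
#' the nearest-edge displacement and are flagged in the `"outside"` attribute.
#'
#' @param A An [affine_transform()] or NULL for identity.
#' @param phi A `diffeo_map` (forward direction) or NULL for identity.
#' @param points A [point_set()].
#' @return A [point_set()] of transformed coordinates with attribute
#'   `"outside"` (logical per point).
#' @export
apply_map_to_points <- function(A, phi, points) {
  d <- point_dim(points)
  out <- points$coords
  outside <- rep(FALSE, nrow(out))
  if (!is.null(phi)) {
    if (length(phi$axes) != d) stop("map dimension does not match points")
    ev <- eval_map(phi, pts_to_axis(out))
    out <- axis_to_pts(ev$positions)
    outside <- ev$outside
  }
  if (!is.null(A)) {
    if (length(A$T) != d) stop("affine dimension does not match points")
    out <- apply_affine(A, out)
  }
  colnames(out) <- colnames(points$coords)
  res <- point_set(out, features = points$features, labels = points$labels)
  attr(res, "outside") <- outside
  res
}

# Euler integration of individual points through the velocity field.
# forward: x <- x + dt v_t(x), t = 1..nt (the time-1 flow applied to points);
# backward: x <- x - dt v_t(x), t = nt..1 (approximate inverse flow).
# pts_ax in axis order; returns list(final, path) where path[[t]] is the
# position before step t (forward) for use in the adjoint.
flow_points <- function(vf, pts_ax, direction = c("forward", "backward"),
                        store = FALSE) {
  direction <- match.arg(direction)
  nt <- vf$nt
  dt <- 1 / nt
  d <- length(vf$axes)
  dims <- lengths(vf$axes)
  x <- pts_ax
  path <- if (store) vector("list", nt) else NULL
  tseq <- if (direction == "forward") seq_len(nt) else rev(seq_len(nt))
  sgn <- if (direction == "forward") 1 else -1
  for (k in seq_len(nt)) {
    t <- tseq[k]
    if (store) path[[k]] <- x
    vt <- array(vf$v[slice_time(vf, t)], c(dims, d))
    g <- grid_interp(vt, vf$axes, x)
    x <- x + sgn * dt * g$values
  }
  list(final = x, path = path, tseq = tseq)
}

# Index helper: logical/integer index extracting timestep t of v.
slice_time <- function(vf, t) {
  d <- length(vf$axes)
  npix <- prod(lengths(vf$axes))
  offset <- (t - 1L) * npix * d
  offset + seq_len(npix * d)
}

#' Resample an image through an alignment map
#'
#' Implements the group action of the map on images: each target pixel `x`
#' takes the source value interpolated at `phi_back(A^{-1} x)`. Linear
#' interpolation; pixels mapping outside the source support receive `fill`
#' (default: per-channel mean of the source border pixels, a proxy for
#' background intensity).
#'
#' @param source A [raster_image()].
#' @param A An [affine_transform()] or NULL for identity.
#' @param phi_back Backward `diffeo_map` (from [integrate_velocity()] with
#'   `direction = "backward"`) or NULL for identity.
#' @param target_axes Axes (list of coordinate vectors) of the output grid.
#' @param fill `"background"`, a numeric vector (one value per channel), or a
#'   single number.
#' @return A [raster_image()] on `target_axes`.
#' @export
resample_image <- function(source, A = NULL, phi_back = NULL, target_axes,
                           fill = "background") {
  d <- length(source$axes)
  nc <- n_channels(source)
  dims_t <- unname(lengths(target_axes))
  pts_ax <- matrix(grid_coords(target_axes), prod(dims_t), d)
  pts <- axis_to_pts(pts_ax)
  if (!is.null(A)) pts <- apply_affine(affine_inverse(A), pts)
  q <- pts_to_axis(pts)
  if (!is.null(phi_back)) {
    ev <- eval_map(phi_back, q)
    q <- ev$positions
  }
  g <- grid_interp(source$values, source$axes, q)
  vals <- g$values
  if (!identical(fill, "none")) {
    fv <- if (identical(fill, "background")) border_mean(source) else
      rep_len(as.numeric(fill), nc)
    if (any(g$outside))
      vals[g$outside, ] <- matrix(fv, sum(g$outside), nc, byrow = TRUE)
  }
  raster_image(array(vals, c(dims_t, nc)), target_axes)
}

# Per-channel mean of the border pixels (background intensity estimate).
border_mean <- function(img) {
  d <- length(img$axes)
  dims <- grid_dims(img)
  nc <- n_channels(img)
  tmp <- array(FALSE, dims)
  for (j in seq_len(d)) {
    si <- slice.index(tmp, j)
    tmp <- tmp | si == 1L | si == dims[j]
  }
  vm <- matrix(img$values, prod(dims), nc)
  colMeans(vm[as.vector(tmp), , drop = FALSE])
}

# Central-difference gradient of a scalar array along one axis (one-sided at
# the boundary), spacing dx.
num_grad_axis <- function(arr, axis, dx) {
  n <- dim(arr)[axis]
  perm <- c(axis, setdiff(seq_along(dim(arr)), axis))
  a <- aperm(arr, perm)
  dm <- dim(a)
  a <- matrix(a, nrow = n)
  g <- a
  if (n >= 3L) {
    g[2:(n - 1), ] <- (a[3:n, , drop = FALSE] - a[1:(n - 2), , drop = FALSE]) / (2 * dx)
  }
  g[1, ] <- (a[2, ] - a[1, ]) / dx
  g[n, ] <- (a[n, ] - a[n - 1, ]) / dx
  dim(g) <- dm
  aperm(g, order(perm))
}

#' Jacobian determinant of a sampled map
#'
#' Central-difference Jacobian determinant at every grid node (one-sided
#' differences at the boundary). Positive values everywhere certify that the
#' sampled map is locally invertible, the defining property of a
#' diffeomorphism.
#'
#' @param phi A `diffeo_map`.
#' @return Numeric array over the map's grid.
#' @export
jacobian_determinant <- function(phi) {
  d <- length(phi$axes)
  dims <- lengths(phi$axes)
  dxs <- axis_spacing(phi$axes)
  npix <- prod(dims)
  pos <- array(phi$positions, c(npix, d))
  J <- array(0, c(npix, d, d))
  for (i in seq_len(d)) {
    comp <- array(pos[, i], dims)
    for (j in seq_len(d)) {
      J[, i, j] <- as.vector(num_grad_axis(comp, j, dxs[j]))
    }
  }
  det_v <- if (d == 2L) {
    J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]
  } else {
    J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
      J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
      J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  }
  array(det_v, dims)
}
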