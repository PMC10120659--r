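# Internal grid utilities: multilinear interpolation on uniform grids, its
# exact transpose (scatter), spatial derivatives of the interpolant, and
# Fourier symbols of the smoothing operator.
#
# Conventions used throughout the package internals:
#   * images / fields are arrays with spatial dims first, channel dim last:
#     dim = c(n1, ..., nd, nc); spatial axis order is (z,)y,x.
#   * `axes` is a list of d strictly increasing, uniformly spaced coordinate
#     vectors (pixel centers, micrometres), in the same order as the dims.
#   * query points are m x d matrices whose columns follow the axis order.
# Outside the grid, fields are extended with the nearest edge value, so the
# positional derivative of the interpolant is zero beyond the boundary.

axis_spacing <- function(axes) {
  vapply(axes, function(ax) {
    if (length(ax) < 2L) return(1)
    ax[2L] - ax[1L]
  }, numeric(1))
}

check_axes <- function(axes, tol = 1e-6) {
  for (ax in axes) {
    if (length(ax) >= 2L) {
      d <- diff(ax)
      if (any(d <= 0)) stop("axis coordinates must be strictly increasing")
      if (max(abs(d - d[1L])) > tol * abs(d[1L]))
        stop("axis coordinates must be uniformly spaced")
    }
  }
  invisible(TRUE)
}

# Corner indices and weights shared by gather, scatter and derivative.
# Returns i0 (m x d, 0-based lower corner), f (m x d fractional offsets in
# [0,1]) and dmask (m x d, FALSE where the query was clamped so positional
# derivatives vanish).
interp_weights <- function(axes, pts) {
  d <- length(axes)
  m <- nrow(pts)
  i0 <- matrix(0L, m, d)
  f <- matrix(0, m, d)
  dmask <- matrix(TRUE, m, d)
  for (j in seq_len(d)) {
    ax <- axes[[j]]
    n <- length(ax)
    if (n == 1L) {
      i0[, j] <- 0L
      f[, j] <- 0
      dmask[, j] <- FALSE
      next
    }
    dx <- ax[2L] - ax[1L]
    u <- (pts[, j] - ax[1L]) / dx
    dmask[, j] <- u > 0 & u < n - 1
    u <- pmin(pmax(u, 0), n - 1)
    lo <- pmin(floor(u), n - 2)
    i0[, j] <- as.integer(lo)
    f[, j] <- u - lo
  }
  list(i0 = i0, f = f, dmask = dmask)
}

# All 2^d corner offsets as a matrix of 0/1 rows.
corner_table <- function(d) {
  as.matrix(expand.grid(rep(list(0:1), d)))
}

# values: array c(dims, nc). Returns list(values = m x nc matrix,
# deriv = m x d x nc array if deriv = TRUE, outside = logical m).
grid_interp <- function(values, axes, pts, deriv = FALSE) {
  d <- length(axes)
  dims <- dim(values)[seq_len(d)]
  nc <- dim(values)[d + 1L]
  if (is.na(nc)) stop("values must carry an explicit channel dimension")
  m <- nrow(pts)
  w <- interp_weights(axes, pts)
  strides <- cumprod(c(1L, dims[-d]))
  npix <- prod(dims)
  vmat <- matrix(values, nrow = npix, ncol = nc)
  corners <- corner_table(d)
  dxs <- axis_spacing(axes)

  out <- matrix(0, m, nc)
  der <- if (deriv) array(0, c(m, d, nc)) else NULL
  for (ci in seq_len(nrow(corners))) {
    cc <- corners[ci, ]
    idx <- rep(1L, m)
    wt <- rep(1, m)
    for (j in seq_len(d)) {
      ij <- w$i0[, j] + cc[j]
      idx <- idx + ij * strides[j]
      wt <- wt * if (cc[j] == 1L) w$f[, j] else 1 - w$f[, j]
    }
    vals <- vmat[idx, , drop = FALSE]
    out <- out + wt * vals
    if (deriv) {
      for (j in seq_len(d)) {
        wj <- rep(1, m)
        for (k in seq_len(d)) {
          if (k == j) next
          wj <- wj * if (cc[k] == 1L) w$f[, k] else 1 - w$f[, k]
        }
        sgn <- if (cc[j] == 1L) 1 else -1
        gj <- wj * sgn / dxs[j]
        gj[!w$dmask[, j]] <- 0
        der[, j, ] <- der[, j, ] + gj * vals
      }
    }
  }
  outside <- rep(FALSE, m)
  for (j in seq_len(d)) {
    ax <- axes[[j]]
    outside <- outside | pts[, j] < ax[1L] | pts[, j] > ax[length(ax)]
  }
  list(values = out, deriv = der, outside = outside)
}

# Exact transpose of the gather in grid_interp: accumulates per-point
# cotangents g (m x nc) onto the grid, returning an array c(dims, nc).
grid_scatter <- function(g, dims, axes, pts) {
  d <- length(axes)
  nc <- ncol(g)
  m <- nrow(g)
  w <- interp_weights(axes, pts)
  strides <- cumprod(c(1L, dims[-d]))
  corners <- corner_table(d)
  ncor <- nrow(corners)

  idx_all <- integer(m * ncor)
  val_all <- matrix(0, m * ncor, nc)
  for (ci in seq_len(ncor)) {
    cc <- corners[ci, ]
    idx <- rep(1L, m)
    wt <- rep(1, m)
    for (j in seq_len(d)) {
      ij <- w$i0[, j] + cc[j]
      idx <- idx + ij * strides[j]
      wt <- wt * if (cc[j] == 1L) w$f[, j] else 1 - w$f[, j]
    }
    rng <- ((ci - 1L) * m + 1L):(ci * m)
    idx_all[rng] <- idx
    val_all[rng, ] <- wt * g
  }
  acc <- rowsum(val_all, idx_all)
  out <- matrix(0, prod(dims), nc)
  out[as.integer(rownames(acc)), ] <- acc
  array(out, c(dims, nc))
}

# n-dimensional FFT helpers (stats::fft is n-dimensional on arrays).
fftn <- function(x) stats::fft(x)
ifftn_real <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

# Discrete Laplacian symbol on the grid:
#   lhat(k) = sum_i (2/dx_i^2) * (1 - cos(2*pi*k_i/n_i))
laplacian_symbol <- function(dims, dxs) {
  lhat <- array(0, dims)
  for (j in seq_along(dims)) {
    n <- dims[j]
    k <- 0:(n - 1)
    vals <- (2 / dxs[j]^2) * (1 - cos(2 * pi * k / n))
    lhat <- lhat + array(vals[slice.index(lhat, j)], dims)
  }
  lhat
}

# Apply a real spectral multiplier to every channel (and optional extra
# trailing dims) of an array whose leading dims match the multiplier.
apply_multiplier <- function(x, mult) {
  dims <- dim(mult)
  xd <- dim(x)
  d <- length(dims)
  rest <- if (length(xd) > d) prod(xd[-seq_len(d)]) else 1L
  xm <- array(x, c(prod(dims), rest))
  out <- xm
  for (r in seq_len(rest)) {
    comp <- array(xm[, r], dims)
    out[, r] <- as.vector(ifftn_real(fftn(comp) * mult))
  }
  array(out, xd)
}
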