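# Synthetic tissue and deformation generators: ground truth for every
# recovery test. All generators are pure functions of (spec, seed).

#' Specification of a synthetic tissue
#'
#' The default fixture emulates a single-cell-resolution section of a
#' structured tissue: cells are drawn from a mixture of spatial Gaussian
#' blobs (anatomical "regions"), each blob having a dominant cell type, and
#' per-cell gene counts follow per-type mean vectors with multiplicative
#' lognormal noise. Coordinates are micrometres centered on the section
#' centroid.
#'
#' @param n_cells Number of cells (default 5000).
#' @param domain Width/height of the tissue in micrometres (default 4000).
#' @param n_blobs Number of spatial blobs (default 8).
#' @param n_types Number of cell types (default 29).
#' @param n_genes Number of genes (default 10).
#' @param blob_sd Spatial sd of each blob (micrometres; default domain / 10).
#' @param dominant_frac Probability that a cell in a blob takes the blob's
#'   dominant type (default 0.55, remainder uniform over other types).
#' @param noise_sdlog sdlog of the per-cell multiplicative expression noise.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 5000, domain = 4000, n_blobs = 8,
                           n_types = 29, n_genes = 10, blob_sd = domain / 10,
                           dominant_frac = 0.55, noise_sdlog = 0.3) {
  stopifnot(n_cells >= 1, n_blobs >= 1, n_types >= 1, n_genes >= 1,
            domain > 0, blob_sd > 0, dominant_frac > 0, dominant_frac <= 1)
  structure(list(n_cells = n_cells, domain = domain, n_blobs = n_blobs,
                 n_types = n_types, n_genes = n_genes, blob_sd = blob_sd,
                 dominant_frac = dominant_frac, noise_sdlog = noise_sdlog),
            class = "synthetic_spec")
}

#' Generate a synthetic tissue
#'
#' Seeded sample from the blob mixture of [synthetic_spec()]: blob centers
#' are placed uniformly in the centered domain, each cell picks a blob, a
#' position around its center, a cell type from the blob's type distribution,
#' and gene counts `Poisson(mean_type,g * lognormal_cell)`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (mandatory).
#' @return A [point_set()] with features (genes) and labels (types), plus
#'   attributes `blob` (per-cell region id), `blob_centers`, `type_means`.
#' @export
generate_tissue <- function(spec = synthetic_spec(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  half <- spec$domain / 2
  margin <- spec$blob_sd
  centers <- cbind(stats::runif(spec$n_blobs, -half + margin, half - margin),
                   stats::runif(spec$n_blobs, -half + margin, half - margin))
  blob_w <- stats::rgamma(spec$n_blobs, shape = 4, rate = 1)
  blob_w <- blob_w / sum(blob_w)
  blob <- sample.int(spec$n_blobs, spec$n_cells, replace = TRUE, prob = blob_w)
  coords <- centers[blob, , drop = FALSE] +
    matrix(stats::rnorm(2L * spec$n_cells, sd = spec$blob_sd), ncol = 2L)
  colnames(coords) <- c("x", "y")

  dominant <- ((seq_len(spec$n_blobs) - 1L) %% spec$n_types) + 1L
  types <- integer(spec$n_cells)
  for (b in seq_len(spec$n_blobs)) {
    i <- which(blob == b)
    if (length(i) == 0L) next
    pr <- rep((1 - spec$dominant_frac) / max(spec$n_types - 1L, 1L),
              spec$n_types)
    pr[dominant[b]] <- if (spec$n_types == 1L) 1 else spec$dominant_frac
    types[i] <- sample.int(spec$n_types, length(i), replace = TRUE, prob = pr)
  }

  type_means <- matrix(stats::rlnorm(spec$n_types * spec$n_genes,
                                     meanlog = 1, sdlog = 0.8),
                       spec$n_types, spec$n_genes)
  noise <- stats::rlnorm(spec$n_cells, meanlog = 0, sdlog = spec$noise_sdlog)
  rates <- type_means[types, , drop = FALSE] * noise
  counts <- matrix(stats::rpois(length(rates), rates), nrow = spec$n_cells)
  colnames(counts) <- paste0("gene", seq_len(spec$n_genes))

  ps <- point_set(coords, features = counts, labels = types)
  attr(ps, "blob") <- blob
  attr(ps, "blob_centers") <- centers
  attr(ps, "type_means") <- type_means
  ps
}

#' Specification of a ground-truth deformation
#'
#' An affine map followed by a sum of Gaussian-bump displacements applied at
#' the affine-transformed positions:
#' `y = A x;  y' = y + sum_j amp_j * exp(-||y - c_j||^2 / (2 scale^2))`.
#' The analytic Lipschitz bound of the bump field,
#' `sum_j ||amp_j|| * exp(-1/2) / scale`, must stay below 1 so the generating
#' deformation is itself a diffeomorphism.
#'
#' @param rotation Rotation angle in degrees (2D).
#' @param scale Isotropic scale factor.
#' @param translation Length-2 translation (micrometres).
#' @param bump_centers m x 2 matrix of bump centers (or NULL for none).
#' @param bump_amps m x 2 matrix of displacement amplitudes (micrometres).
#' @param bump_scale Bump width (micrometres).
#' @return List of class `deformation_spec`.
#' @export
deformation_spec <- function(rotation = 0, scale = 1, translation = c(0, 0),
                             bump_centers = NULL, bump_amps = NULL,
                             bump_scale = 500) {
  th <- rotation * pi / 180
  L <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  spec <- list(L = L, translation = translation,
               bump_centers = if (is.null(bump_centers)) NULL else as.matrix(bump_centers),
               bump_amps = if (is.null(bump_amps)) NULL else as.matrix(bump_amps),
               bump_scale = bump_scale)
  if (!is.null(spec$bump_centers)) {
    lip <- sum(sqrt(rowSums(spec$bump_amps^2))) * exp(-0.5) / bump_scale
    if (lip >= 1)
      stop(sprintf("bump field is not diffeomorphic (Lipschitz bound %.2f >= 1); reduce amplitudes or widen bump_scale", lip))
    spec$lipschitz <- lip
  }
  structure(spec, class = "deformation_spec")
}

bump_displacement <- function(y, spec) {
  u <- matrix(0, nrow(y), ncol(y))
  if (is.null(spec$bump_centers)) return(u)
  for (j in seq_len(nrow(spec$bump_centers))) {
    r2 <- rowSums(sweep(y, 2L, spec$bump_centers[j, ])^2)
    g <- exp(-r2 / (2 * spec$bump_scale^2))
    u <- u + outer(g, spec$bump_amps[j, ])
  }
  u
}

#' Apply a ground-truth deformation to points
#'
#' Applies the affine, then the analytic Gaussian-bump displacement field.
#' The returned set preserves cell order, so row i of the output corresponds
#' to row i of the input: an exact per-cell correspondence for measuring
#' recovery error.
#'
#' @param points A [point_set()].
#' @param spec A [deformation_spec()].
#' @return A [point_set()] of deformed positions with attribute
#'   `"original_coords"`.
#' @export
deform_points <- function(points, spec) {
  y <- sweep(points$coords %*% t(spec$L), 2L, spec$translation, "+")
  y2 <- y + bump_displacement(y, spec)
  colnames(y2) <- colnames(points$coords)
  out <- point_set(y2, features = points$features, labels = points$labels)
  attr(out, "original_coords") <- points$coords
  out
}

#' Invert the bump displacement by fixed-point iteration
#'
#' Solves `y = x + u(x)` for `x` given deformed positions `y` (the bump part
#' of [deform_points()]); converges geometrically because the bump field's
#' Lipschitz bound is below 1. The affine is then inverted in closed form.
#'
#' @param points Deformed [point_set()].
#' @param spec The generating [deformation_spec()].
#' @param tol Convergence tolerance in micrometres.
#' @param maxit Maximum iterations.
#' @return A [point_set()] of recovered original positions.
#' @export
invert_deformation <- function(points, spec, tol = 1e-9, maxit = 200) {
  y <- points$coords
  x <- y
  for (it in seq_len(maxit)) {
    xn <- y - bump_displacement(x, spec)
    if (max(abs(xn - x)) < tol) {
      x <- xn
      break
    }
    x <- xn
  }
  orig <- sweep(x, 2L, spec$translation) %*% t(solve(spec$L))
  colnames(orig) <- colnames(points$coords)
  point_set(orig, features = points$features, labels = points$labels)
}

#' Remove cells on one side of a half-plane
#'
#' Simulates a partially matched tissue section: cells with
#' `<coords, normal> > offset` are removed. The cut is recorded so masking
#' tests know exactly which source cells lost their counterpart.
#'
#' @param points A [point_set()].
#' @param normal Length-d normal vector of the cutting half-plane.
#' @param offset Scalar: cells with projection greater than this are removed.
#' @return The kept [point_set()] with attributes `"removed"` (indices into
#'   the input) and `"cut"` (list with normal and offset).
#' @export
cut_section <- function(points, normal, offset) {
  proj <- as.vector(points$coords %*% normal)
  keep <- proj <= offset
  if (!any(keep)) stop("cut removes every cell")
  out <- point_set(points$coords[keep, , drop = FALSE],
                   features = points$features[keep, , drop = FALSE],
                   labels = points$labels[keep])
  attr(out, "removed") <- which(!keep)
  attr(out, "kept") <- which(keep)
  attr(out, "cut") <- list(normal = normal, offset = offset)
  out
}

# Shared blob-intensity field so 2D slices of generated volumes can be
# checked against the same analytic expression.
blob_intensity <- function(pts_ax, centers_ax, sds, amps) {
  val <- rep(0, nrow(pts_ax))
  for (b in seq_len(nrow(centers_ax))) {
    r2 <- rowSums(sweep(pts_ax, 2L, centers_ax[b, ])^2)
    val <- val + amps[b] * exp(-r2 / (2 * sds[b]^2))
  }
  val
}

#' Generate a synthetic intensity volume with region labels
#'
#' A smooth 3D sum-of-Gaussian-blobs intensity (standing in for an atlas
#' intensity volume) plus integer region labels on the same grid: voxels with
#' intensity above `label_threshold` are labelled by their nearest blob,
#' others are background (0).
#'
#' @param dims Grid size (nz, ny, nx).
#' @param dx Voxel size in micrometres (default 50).
#' @param n_blobs Number of blobs (default 4).
#' @param seed Integer seed.
#' @param label_threshold Intensity cutoff for foreground labels.
#' @return List with `intensity` ([raster_image()], 1 channel), `labels`
#'   ([label_volume()]), `centers` (axis-order blob centers), `sds`, `amps`.
#' @export
generate_volume <- function(dims = c(20, 32, 32), dx = 50, n_blobs = 4, seed,
                            label_threshold = 0.2) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  axes <- lapply(dims, function(n) (seq_len(n) - (n + 1) / 2) * dx)
  ext <- vapply(axes, function(ax) diff(range(ax)), numeric(1))
  centers <- vapply(seq_len(3L), function(j)
    stats::runif(n_blobs, -0.3 * ext[j], 0.3 * ext[j]), numeric(n_blobs))
  centers <- matrix(centers, n_blobs, 3L)
  sds <- stats::runif(n_blobs, 0.12, 0.2) * min(ext)
  amps <- stats::runif(n_blobs, 0.7, 1)
  pts <- matrix(grid_coords(axes), prod(dims), 3L)
  val <- blob_intensity(pts, centers, sds, amps)
  # nearest blob in blob-sd units
  d2 <- vapply(seq_len(n_blobs), function(b)
    rowSums(sweep(pts, 2L, centers[b, ])^2) / sds[b]^2, numeric(nrow(pts)))
  lab <- max.col(-d2, ties.method = "first")
  lab[val < label_threshold] <- 0L
  list(intensity = raster_image(array(val, dims), axes),
       labels = label_volume(array(as.integer(lab), dims), axes),
       centers = centers, sds = sds, amps = amps)
}
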