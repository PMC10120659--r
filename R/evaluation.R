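#' Aggregate cells into square grid pixels
#'
#' Partitions cells into `grid_size` x `grid_size` micrometre pixels (index =
#' `floor((coord - min) / grid_size)` per axis) and sums the feature matrix
#' per occupied pixel. Used to compare gene expression at matched spatial
#' locations across datasets with differing cell numbers.
#'
#' @param points A [point_set()] with features.
#' @param grid_size Pixel width in micrometres (default 200).
#' @return List of class `aggregated_matrix`: `unit_ids` (pixel key strings),
#'   `unit_positions` (pixel-center coordinates, point order),
#'   `features` (units x g matrix of sums), `cell_units` (per-cell unit index,
#'   NA when unassigned).
#' @export
grid_aggregate <- function(points, grid_size = 200) {
  if (is.null(points$features)) stop("grid_aggregate requires features")
  co <- points$coords
  d <- ncol(co)
  mins <- apply(co, 2L, min)
  idx <- floor(sweep(co, 2L, mins) / grid_size)
  key <- apply(idx, 1L, paste, collapse = "_")
  ids <- sort(unique(key))
  unit_of_cell <- match(key, ids)
  feats <- rowsum(points$features, unit_of_cell)
  pos_list <- rowsum(sweep(idx * grid_size, 2L, mins + grid_size / 2, "+"),
                     unit_of_cell)
  counts <- tabulate(unit_of_cell, length(ids))
  first <- match(seq_along(ids), unit_of_cell)
  pos <- sweep(idx[first, , drop = FALSE] * grid_size, 2L,
               mins + grid_size / 2, "+")
  colnames(pos) <- colnames(co)
  structure(list(unit_ids = ids, unit_positions = pos,
                 features = unname(as.matrix(feats)),
                 cell_units = unit_of_cell, grid_size = grid_size),
            class = "aggregated_matrix")
}

#' Aggregate cells into pseudospots around given centers
#'
#' A cell belongs to a spot when its distance to the spot center is less than
#' `radius`; when capture spots overlap, the cell is assigned to the nearest
#' qualifying center only, so each cell contributes to at most one spot.
#'
#' @param points A [point_set()] with features.
#' @param centers k x d matrix of spot centers (micrometres, point order).
#' @param radius Spot radius (micrometres).
#' @return An `aggregated_matrix` over all `k` spots (empty spots have
#'   zero-sum rows); `cell_units` is NA for unassigned cells.
#' @export
pseudospot_aggregate <- function(points, centers, radius) {
  if (is.null(points$features)) stop("pseudospot_aggregate requires features")
  stopifnot(radius > 0)
  centers <- as.matrix(centers)
  co <- points$coords
  if (ncol(centers) != ncol(co)) stop("centers must match point dimension")
  k <- nrow(centers)
  # squared distances cells x spots (fixture scales: thousands x hundreds)
  d2 <- outer(rowSums(co^2), rep(1, k)) - 2 * co %*% t(centers) +
    outer(rep(1, nrow(co)), rowSums(centers^2))
  d2[d2 < 0] <- 0
  best <- max.col(-d2, ties.method = "first")
  bestd <- d2[cbind(seq_len(nrow(co)), best)]
  unit <- ifelse(sqrt(bestd) < radius, best, NA_integer_)
  feats <- matrix(0, k, ncol(points$features))
  ok <- !is.na(unit)
  if (any(ok)) {
    acc <- rowsum(points$features[ok, , drop = FALSE], unit[ok])
    feats[as.integer(rownames(acc)), ] <- acc
  }
  structure(list(unit_ids = as.character(seq_len(k)), unit_positions = centers,
                 features = feats, cell_units = unit, radius = radius),
            class = "aggregated_matrix")
}

#' Counts-per-million + log10 normalization
#'
#' Per unit (row): counts scaled to sum to 1e6, then `log10(x + 1)`.
#' Zero-total rows are returned as zeros with a warning.
#'
#' @param mat Non-negative units x features matrix (or `aggregated_matrix`).
#' @return Matrix of normalized values.
#' @export
cpm_log_normalize <- function(mat) {
  if (inherits(mat, "aggregated_matrix")) mat <- mat$features
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("counts must be non-negative")
  tot <- rowSums(mat)
  zero <- tot == 0
  if (any(zero)) warning(sprintf("%d zero-total rows left as zeros", sum(zero)))
  tot[zero] <- 1
  log10(mat * (1e6 / tot) + 1)
}

#' Per-feature cosine similarity between two aggregated matrices
#'
#' For each feature column, `cos = <a, b> / (||a|| ||b||)` across matched
#' units. Columns that are zero in both matrices are undefined and returned
#' as NA.
#'
#' @param A,B Matrices with identical dimensions and matched unit rows.
#' @return Numeric vector (one value per feature) in \[-1, 1\] or NA.
#' @export
cosine_similarity_per_feature <- function(A, B) {
  if (inherits(A, "aggregated_matrix")) A <- A$features
  if (inherits(B, "aggregated_matrix")) B <- B$features
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("matrices must have matching dimensions")
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2)) * sqrt(colSums(B^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Root-mean-square error between paired landmarks
#'
#' `sqrt(mean_i ||s_i - t_i||^2)` in micrometres; the headline measure of
#' alignment accuracy at manually identified structures.
#'
#' @param lm A [landmark_set()] holding aligned source vs target positions.
#' @return RMSE in micrometres.
#' @export
landmark_rmse <- function(lm) {
  sqrt(mean(rowSums((lm$source_pts - lm$target_pts)^2)))
}

#' Cell-type composition of a region
#'
#' @param labels Per-cell type labels within the region.
#' @param levels The full set of type levels (fixes the vector length K).
#' @return Proportion vector over `levels` (zero vector for an empty region).
#' @export
composition_vector <- function(labels, levels) {
  if (length(labels) == 0L) return(stats::setNames(rep(0, length(levels)), levels))
  tab <- table(factor(labels, levels = levels))
  as.numeric(tab) / length(labels)
}

#' Euclidean distance between composition vectors
#'
#' @param r1,r2 Proportion vectors of equal length K.
#' @return `||r1 - r2||_2`.
#' @export
composition_distance <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("composition vectors must share K")
  sqrt(sum((r1 - r2)^2))
}

#' Random region of matched size
#'
#' Draws a uniform integer-coordinate center inside the bounding box of the
#' points and takes the `n_cells` nearest cells; the size-matched null used to
#' judge whether annotated regions are more consistent than chance.
#'
#' @param points A [point_set()].
#' @param n_cells Region size.
#' @param seed Integer seed.
#' @return Integer vector of cell indices.
#' @export
random_region <- function(points, n_cells, seed) {
  co <- points$coords
  if (n_cells > nrow(co)) stop("n_cells exceeds the number of cells")
  set.seed(seed)
  center <- vapply(seq_len(ncol(co)), function(j) {
    rng <- floor(range(co[, j]))
    as.numeric(sample(seq(rng[1L], rng[2L]), 1L))
  }, numeric(1))
  d2 <- rowSums(sweep(co, 2L, center)^2)
  order(d2)[seq_len(n_cells)]
}

#' Expand a region by k-nearest neighbors
#'
#' Returns the union of the region with the k nearest neighbors (among all
#' cells) of every member cell; always a superset of the input. With k = 100
#' on typical single-cell densities this grows the boundary by roughly 100
#' micrometres.
#'
#' @param points A [point_set()].
#' @param region Integer vector of member cell indices.
#' @param k Number of neighbors per member (default 100). `k >= n` returns
#'   all cells.
#' @return Integer vector of cell indices (sorted).
#' @export
expand_region_knn <- function(points, region, k = 100) {
  co <- points$coords
  n <- nrow(co)
  region <- sort(unique(as.integer(region)))
  if (k <= 0) return(region)
  if (k >= n) return(seq_len(n))
  sel <- co[region, , drop = FALSE]
  d2 <- outer(rowSums(sel^2), rep(1, n)) - 2 * sel %*% t(co) +
    outer(rep(1, nrow(sel)), rowSums(co^2))
  d2[cbind(seq_along(region), region)] <- Inf # a cell is not its own neighbor
  nbrs <- apply(d2, 1L, function(r) order(r)[seq_len(k)])
  sort(unique(c(region, as.vector(nbrs))))
}

#' Shannon entropy of a composition vector
#'
#' `H = -sum p ln p` (natural log, `0 ln 0 = 0`): 0 for a one-hot composition
#' and `ln K` for a uniform one. Lower entropy indicates a region dominated by
#' few cell types.
#'
#' @param comp Proportion vector.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(comp) {
  if (any(comp < 0)) stop("proportions must be non-negative")
  s <- sum(comp)
  if (s == 0) return(0)
  p <- comp / s
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (h == 0) 0 else h # avoid IEEE negative zero for one-hot inputs
}
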