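#' Construct a point set of cell positions
#'
#' A `point_set` holds cell centroids in physical micrometre coordinates,
#' optionally with a per-cell feature matrix (for example gene counts) and a
#' categorical label per cell (for example a cell type).
#'
#' @param coords Numeric matrix or data frame, n x d, with d = 2 or 3.
#'   Columns are interpreted in (x, y\[, z\]) order; column names are set to
#'   "x", "y" (and "z").
#' @param features Optional non-negative numeric matrix with n rows (cells by
#'   features, for example a cell-by-gene count matrix).
#' @param labels Optional vector of length n with a categorical label per cell.
#' @return An object of class `point_set` with elements `coords`, `features`,
#'   `labels`.
#' @export
point_set <- function(coords, features = NULL, labels = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  d <- ncol(coords)
  if (!d %in% c(2L, 3L)) stop("coords must have 2 or 3 columns")
  if (nrow(coords) == 0L) stop("point set is empty")
  bad <- which(!is.finite(coords), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite coordinate at row %d", bad[1L, 1L]))
  colnames(coords) <- c("x", "y", "z")[seq_len(d)]
  if (!is.null(features)) {
    features <- as.matrix(features)
    storage.mode(features) <- "double"
    if (nrow(features) != nrow(coords))
      stop("features must have one row per point")
    if (any(!is.finite(features)) || any(features < 0))
      stop("features must be finite and non-negative")
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(coords))
      stop("labels must have one entry per point")
  }
  structure(list(coords = coords, features = features, labels = labels),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("point_set: %d cells in %dD", nrow(x$coords), ncol(x$coords)))
  if (!is.null(x$features))
    cat(sprintf(", %d features", ncol(x$features)))
  if (!is.null(x$labels))
    cat(sprintf(", %d label classes", length(unique(x$labels))))
  cat("\n")
  invisible(x)
}

n_points <- function(points) nrow(points$coords)

point_dim <- function(points) ncol(points$coords)

# Points are stored user-facing in (x, y[, z]) order; grids use axis order
# ((z,) y, x). Conversion is a column reversal.
pts_to_axis <- function(coords) coords[, rev(seq_len(ncol(coords))), drop = FALSE]
axis_to_pts <- function(coords) coords[, rev(seq_len(ncol(coords))), drop = FALSE]
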