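#' Read a cell-position table
#'
#' Reads a delimited table of cell centroids in micrometres. Count columns, if
#' named, become the feature matrix; a label column becomes per-cell labels.
#'
#' @param path File path.
#' @param x_col,y_col,z_col Coordinate column names (`z_col = NULL` for 2D).
#' @param count_cols Character vector of feature-count column names, or NULL.
#' @param label_col Optional label column name.
#' @param sep Field delimiter (default comma).
#' @return A [point_set()].
#' @export
read_points_csv <- function(path, x_col = "x", y_col = "y", z_col = NULL,
                            count_cols = NULL, label_col = NULL, sep = ",") {
  dt <- data.table::fread(path, sep = sep, data.table = FALSE)
  need <- c(x_col, y_col, z_col, count_cols, label_col)
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0L)
    stop(sprintf("column '%s' not found in %s", missing_cols[1L], path))
  coord_cols <- c(x_col, y_col, z_col)
  coords <- suppressWarnings(
    matrix(as.numeric(as.matrix(dt[coord_cols])), nrow = nrow(dt),
           ncol = length(coord_cols)))
  bad <- which(!is.finite(coords), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("unparseable/non-finite coordinate at line %d of %s",
                 bad[1L, 1L] + 1L, path))
  features <- if (!is.null(count_cols)) as.matrix(dt[count_cols]) else NULL
  labels <- if (!is.null(label_col)) dt[[label_col]] else NULL
  point_set(coords, features = features, labels = labels)
}

#' Write a cell-position table
#'
#' @param points A [point_set()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_points_csv <- function(points, path) {
  df <- as.data.frame(points$coords)
  if (!is.null(points$features)) {
    fm <- as.data.frame(points$features)
    if (is.null(colnames(points$features)))
      names(fm) <- paste0("count", seq_len(ncol(fm)))
    df <- cbind(df, fm)
  }
  if (!is.null(points$labels)) df$label <- points$labels
  data.table::fwrite(df, path)
  invisible(path)
}

#' Write aligned cells with flags and lifted labels
#'
#' Writes one row per cell with the original coordinates (`x`, `y`\[, `z`\]),
#' the aligned coordinates (`x_aligned`, ...), an optional matching flag
#' (`matched`, empty when no mask was computed) and an optional lifted
#' annotation id (`region_id`).
#'
#' @param points Original [point_set()].
#' @param aligned Transformed [point_set()] (same cells, same order).
#' @param path Output path.
#' @param flags Optional logical vector from [matching_mask()].
#' @param labels Optional integer vector from [lift_over_labels()].
#' @return Invisibly, the path.
#' @export
write_aligned_points <- function(points, aligned, path, flags = NULL,
                                 labels = NULL) {
  if (n_points(points) != n_points(aligned))
    stop("points and aligned must have the same number of cells")
  df <- as.data.frame(points$coords)
  al <- as.data.frame(aligned$coords)
  names(al) <- paste0(names(al), "_aligned")
  df <- cbind(df, al)
  df$matched <- if (is.null(flags)) NA else flags
  if (!is.null(labels)) df$region_id <- labels
  if (!is.null(points$labels)) df$label <- points$labels
  ok <- tryCatch({
    data.table::fwrite(df, path)
    TRUE
  }, error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                      conditionMessage(e))))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a PNG or TIFF image as a raster image
#'
#' Values are scaled to \[0, 1\], channels last. Physical pixel size comes
#' from a side-car JSON written by [write_image()] (fields `origin`,
#' `spacing`, axis order (y, x)) or from the `dx`/`origin` arguments; it is
#' never guessed from the file alone.
#'
#' @param path PNG or TIFF file.
#' @param dx Pixel size in micrometres (scalar or per-axis (y, x)); ignored
#'   when a side-car file exists.
#' @param origin Physical position of the first pixel center (y, x), default
#'   c(0, 0).
#' @return A [raster_image()].
#' @export
read_image <- function(path, dx = NULL, origin = c(0, 0)) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      v <- tiff::readTIFF(path)
      if (is.list(v)) v <- v[[1L]]
      v
    },
    stop(sprintf("unsupported image format '%s'", ext))
  )
  if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    dx <- meta$spacing
    origin <- meta$origin
  }
  if (is.null(dx))
    stop("pixel size unknown: pass dx= or provide a side-car JSON")
  dx <- rep_len(dx, 2L)
  origin <- rep_len(origin, 2L)
  axes <- list(origin[1L] + (seq_len(dim(vals)[1L]) - 1L) * dx[1L],
               origin[2L] + (seq_len(dim(vals)[2L]) - 1L) * dx[2L])
  raster_image(vals, axes)
}

#' Write a raster image to TIFF (or PNG) with a coordinate side-car
#'
#' Writes the image (clipped to \[0, 1\]) plus `<path>.json` recording the
#' axis origins and spacings so [read_image()] restores physical coordinates.
#' TIFF output uses 32-bit float samples and round-trips losslessly; PNG is
#' quantized to 16 bits.
#'
#' @param img A 2D [raster_image()] with 1, 3 or 4 channels.
#' @param path Output file, extension `.tif`/`.tiff`/`.png`.
#' @return Invisibly, the path.
#' @export
write_image <- function(img, path) {
  stopifnot(length(img$axes) == 2L)
  vals <- img$values
  if (dim(vals)[3L] == 1L) dim(vals) <- dim(vals)[1:2]
  vals <- pmin(pmax(vals, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(vals, path),
    tif = ,
    tiff = tiff::writeTIFF(vals, path, bits.per.sample = 32L,
                           compression = "none"),
    stop(sprintf("unsupported image format '%s'", ext))
  )
  meta <- list(origin = vapply(img$axes, `[`, numeric(1), 1L),
               spacing = img$dx,
               axis_order = names(img$axes))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

# --- minimal NRRD (detached header not supported; raw and gzip encodings) ---

nrrd_types <- c("uint8" = 1L, "int16" = 2L, "uint16" = 2L,
                "int32" = 4L, "uint32" = 4L, "int64" = 8L)

#' Read an NRRD volume of integer labels
#'
#' Minimal NRRD0004 reader for integer payloads with `raw` or `gzip`
#' encoding. Axis coordinates are reconstructed from `spacings` (or the
#' diagonal of `space directions`) and `space origin`; the file's axis order
#' (fastest first) maps directly onto the array's dimensions.
#'
#' @param path NRRD file.
#' @param spacing Fallback per-axis spacing when the header has none.
#' @return A [label_volume()].
#' @export
read_nrrd_labels <- function(path, spacing = NULL) {
  nr <- read_nrrd(path, spacing = spacing)
  label_volume(nr$data, nr$axes)
}

read_nrrd <- function(path, spacing = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of NRRD header")
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- strsplit(line, ": ?", fixed = FALSE)[[1L]]
    fields[[tolower(kv[1L])]] <- paste(kv[-1L], collapse = ":")
  }
  sizes <- as.integer(strsplit(fields$sizes, " +")[[1L]])
  type <- gsub(" ", "", fields$type)
  type <- switch(type,
                 "unsignedchar" = , "uchar" = "uint8",
                 "short" = , "shortint" = "int16",
                 "unsignedshort" = "uint16",
                 "int" = , "signedint" = "int32",
                 "unsignedint" = "uint32",
                 type)
  if (!type %in% names(nrrd_types))
    stop(sprintf("unsupported NRRD type '%s' (integer labels expected)", type))
  bytes <- nrrd_types[[type]]
  endian <- if (!is.null(fields$endian) && fields$endian == "big") "big" else "little"
  n <- prod(sizes)
  enc <- fields$encoding %||% "raw"
  payload <- readBin(con, "raw", n = 1e9)
  if (enc == "gzip" || enc == "gz") {
    payload <- memDecompress(payload, type = "gzip")
  } else if (enc != "raw") {
    stop(sprintf("unsupported NRRD encoding '%s'", enc))
  }
  signed <- !startsWith(type, "u")
  vals <- readBin(payload, "integer", n = n, size = bytes,
                  signed = if (bytes < 4) signed else TRUE, endian = endian)
  sp <- NULL
  if (!is.null(fields$spacings)) {
    sp <- as.numeric(strsplit(trimws(fields$spacings), " +")[[1L]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1L]]
    mat <- vapply(vecs, function(v) {
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1L]])
    }, numeric(length(sizes)))
    sp <- sqrt(colSums(mat^2))
  }
  if (is.null(sp)) {
    if (is.null(spacing))
      stop("NRRD header has no spacing; pass spacing= explicitly")
    sp <- rep_len(spacing, length(sizes))
  }
  orig <- rep(0, length(sizes))
  if (!is.null(fields[["space origin"]])) {
    orig <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]),
                                ",")[[1L]])
  }
  axes <- lapply(seq_along(sizes), function(j)
    orig[j] + (seq_len(sizes[j]) - 1L) * sp[j])
  list(data = array(vals, sizes), axes = axes)
}

#' Write an integer volume as NRRD
#'
#' @param vol A [label_volume()] (or list with `labels` array and `axes`).
#' @param path Output file.
#' @param encoding `"raw"` or `"gzip"`.
#' @return Invisibly, the path.
#' @export
write_nrrd <- function(vol, path, encoding = c("raw", "gzip")) {
  encoding <- match.arg(encoding)
  data <- vol$labels
  axes <- vol$axes
  sizes <- dim(data)
  sp <- axis_spacing(axes)
  orig <- vapply(axes, `[`, numeric(1), 1L)
  hdr <- c(
    "NRRD0004",
    "type: int32",
    sprintf("dimension: %d", length(sizes)),
    sprintf("sizes: %s", paste(sizes, collapse = " ")),
    sprintf("spacings: %s", paste(format(sp, scientific = FALSE), collapse = " ")),
    sprintf("space origin: (%s)", paste(format(orig, scientific = FALSE), collapse = ",")),
    "endian: little",
    sprintf("encoding: %s", encoding),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  payload <- writeBin(as.integer(data), raw(), size = 4L, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  writeBin(payload, con)
  invisible(path)
}

# --- transform container ---

#' Save a solved alignment to a JSON container
#'
#' Serializes the affine matrix, velocity-field samples and grid metadata so
#' an alignment can be re-applied to new points without re-solving.
#'
#' @param result An `alignment_result`.
#' @param path Output `.json` path.
#' @return Invisibly, the path.
#' @export
write_alignment <- function(result, path) {
  obj <- list(
    format = "diffeost-transform-v1",
    d = length(result$v$axes),
    embed_3d = result$embed_3d,
    affine = result$A$matrix,
    velocity = list(
      dims = lengths(result$v$axes),
      origin = vapply(result$v$axes, `[`, numeric(1), 1L),
      spacing = result$v$dx,
      nt = result$v$nt, a = result$v$a, p = result$v$p,
      samples = as.vector(result$v$v)
    ),
    target_axes = lapply(result$target_axes,
                         function(ax) c(ax[1L], ax[2L] - ax[1L], length(ax)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an alignment container written by [write_alignment()]
#'
#' @param path JSON transform container.
#' @return A reduced `alignment_result` (affine + velocity field + grids)
#'   usable with [transform_points()] and [lift_over_labels()].
#' @export
read_alignment <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "diffeost-transform-v1"))
    stop("not a diffeost transform container")
  d <- obj$d
  vx <- obj$velocity
  axes <- lapply(seq_len(d), function(j)
    vx$origin[j] + (seq_len(vx$dims[j]) - 1L) * vx$spacing[j])
  vf <- velocity_field(array(vx$samples, c(vx$dims, d, vx$nt)), axes,
                       a = vx$a, p = vx$p)
  tgt_axes <- lapply(obj$target_axes, function(m)
    m[1L] + (seq_len(m[3L]) - 1L) * m[2L])
  structure(list(A = affine_transform(matrix = obj$affine), v = vf,
                 loss_history = NULL, W = NULL, theta = NULL,
                 source_axes = NULL, target_axes = tgt_axes,
                 embed_3d = isTRUE(obj$embed_3d), config = NULL),
            class = "alignment_result")
}

#' Read a solver configuration file
#'
#' JSON (or YAML-free TOML-like JSON) config whose keys mirror the solver's
#' canonical parameter names: `dx, sigmaM, sigmaR, sigmaP, sigmaA, sigmaB, a,
#' p, niter, diffeo_start, nt, epL, epT, epV, pointsI, pointsJ, muB, muA, L,
#' T, A`. Unknown keys are an error.
#'
#' @param path JSON file.
#' @return A [solver_config()].
#' @export
read_solver_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  solver_config_from_list(obj)
}

solver_config_from_list <- function(obj) {
  map <- c(dx = "dx", sigmaM = "sigma_M", sigmaR = "sigma_R",
           sigmaP = "sigma_P", sigmaA = "sigma_A", sigmaB = "sigma_B",
           a = "a", p = "p", niter = "niter", diffeo_start = "diffeo_start",
           nt = "nt", epL = "epL", epT = "epT", epV = "epV",
           pointsI = "pointsI", pointsJ = "pointsJ", muB = "muB",
           muA = "muA", L = "L0", T = "T0", A = "A0",
           contrast_degree = "contrast_degree", seed = "seed",
           verbose = "verbose")
  unknown <- setdiff(names(obj), names(map))
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key '%s'", unknown[1L]))
  args <- obj
  names(args) <- map[names(obj)]
  for (nm in c("pointsI", "pointsJ", "L0", "A0"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.matrix(args[[nm]])
  do.call(solver_config, args)
}
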