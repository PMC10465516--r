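#' Volumetric image containers
#'
#' `volume3d()` wraps a 3D numeric array together with its grid metadata
#' (voxel spacing in mm, physical origin in mm). `label_volume()` is the
#' integer-valued counterpart used for lung masks, lobe segmentations and
#' integrity masks; it additionally records the declared label set.
#'
#' All volumes are kept in a single canonical axis order (x, y, z) with
#' 0-based voxel index `(0,0,0)` located at `origin`; files read from disk are
#' reoriented at load time so downstream adjacency and cropping logic never
#' depends on the on-disk orientation.
#'
#' @param data 3D numeric (or integer, for labels) array.
#' @param spacing Numeric length-3, voxel size in mm; strictly positive.
#' @param origin Numeric length-3, physical position of voxel (0,0,0) in mm.
#' @param labels Optional integer vector declaring the permitted label set;
#'   defaults to the labels present in `data`.
#' @return An object of class `volume3d` (and `label_volume` for labels).
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("volume3d: `data` must have exactly 3 spatial dimensions, got ",
         length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume3d: spacing must be 3 strictly positive values")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin)),
    class = "volume3d")
}

#' @rdname volume3d
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         labels = NULL) {
  storage.mode(data) <- "integer"
  if (any(data < 0L, na.rm = TRUE))
    stop("label_volume: labels must be non-negative integers")
  v <- volume3d(data, spacing, origin)
  v$labels <- if (is.null(labels)) sort(unique(as.integer(data)))
              else sort(unique(as.integer(labels)))
  if (!all(unique(as.integer(data)) %in% v$labels))
    stop("label_volume: data contains values outside the declared label set")
  class(v) <- c("label_volume", "volume3d")
  v
}

#' @export
print.volume3d <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label_volume" else "volume3d"
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 6), collapse = "x"),
              paste(signif(x$origin, 6), collapse = ", ")))
  if (inherits(x, "label_volume"))
    cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  rng <- range(x$data)
  cat(sprintf("  value range: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

is_label <- function(vol) inherits(vol, "label_volume")

#' Read a volumetric image
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) via RNifti, or an uncompressed local-raw
#' MetaImage (`.mha`/`.mhd`). Integer-typed files (and floating-point files
#' whose values are all non-negative integers below 256) are returned as
#' [label_volume()]; everything else as [volume3d()].
#'
#' @param path Path to the image file.
#' @param as_labels Force label (`TRUE`) or scalar (`FALSE`) interpretation;
#'   `NA` (default) decides from the stored datatype.
#' @return A [volume3d()] or [label_volume()].
#' @export
read_volume <- function(path, as_labels = NA) {
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  low <- tolower(path)
  if (grepl("\\.(nii|nii\\.gz)$", low)) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("read_volume: unreadable NIfTI '",
                                             path, "': ", conditionMessage(e)))
    arr <- as.array(img)
    arr <- array(as.double(arr), dim(arr))   # drop RNifti's internal attributes
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
      arr <- array(arr, dim(arr)[1:3])
    if (length(dim(arr)) != 3L)
      stop("read_volume: '", path, "' is not a 3D image (dims: ",
           paste(dim(arr), collapse = "x"), ")")
    pd <- RNifti::pixdim(img)[1:3]
    hdr <- RNifti::niftiHeader(img)
    origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
    integer_coded <- hdr$datatype %in% c(2L, 4L, 8L, 256L, 512L, 768L)
  } else if (grepl("\\.(mha|mhd)$", low)) {
    m <- read_metaimage(path)
    arr <- m$data; pd <- m$spacing; origin <- m$origin
    integer_coded <- m$integer_coded
  } else {
    stop("read_volume: unsupported format for '", path,
         "' (expected .nii, .nii.gz, .mha or .mhd)")
  }
  lab <- if (is.na(as_labels)) integer_coded else isTRUE(as_labels)
  if (lab) label_volume(arr, spacing = pd, origin = origin)
  else volume3d(arr, spacing = pd, origin = origin)
}

#' Write a volume to NIfTI
#'
#' Label volumes are stored as unsigned 8-bit; scalar volumes as 32-bit float.
#'
#' @param vol A [volume3d()] or [label_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  dt <- if (is_label(vol)) "uint8" else "float"
  if (is_label(vol) && max(vol$data) > 255L) dt <- "int16"
  hdr <- list(pixdim = c(1, vol$spacing, 0, 0, 0, 0),
              qform_code = 1L,
              qoffset_x = vol$origin[1], qoffset_y = vol$origin[2],
              qoffset_z = vol$origin[3])
  img <- RNifti::asNifti(vol$data, reference = hdr, datatype = dt)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

# Minimal MetaImage reader: ASCII header, uncompressed, ElementDataFile LOCAL
# or a sibling .raw file. Covers the subset emitted by common converters.
read_metaimage <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- list(); data_file <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("read_volume: truncated MetaImage header in ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("read_volume: malformed MetaImage line: ", line)
    key <- kv[2]; val <- trimws(kv[3])
    hdr[[key]] <- val
    if (key == "ElementDataFile") { data_file <- val; break }
  }
  ndims <- as.integer(hdr$NDims %||% "0")
  if (ndims != 3L)
    stop("read_volume: '", path, "' is not a 3D image (NDims=", ndims, ")")
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("read_volume: compressed MetaImage not supported: ", path)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr$ElementType %||% "MET_FLOAT"
  info <- switch(type,
    MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE, int = TRUE),
    MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE,  int = TRUE),
    MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE,  int = TRUE),
    MET_USHORT = list(what = "integer", size = 2L, signed = FALSE, int = TRUE),
    MET_INT    = list(what = "integer", size = 4L, signed = TRUE,  int = TRUE),
    MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE,  int = FALSE),
    MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE,  int = FALSE),
    stop("read_volume: unsupported MetaImage ElementType: ", type))
  n <- prod(dims)
  if (toupper(data_file) == "LOCAL") {
    raw <- readBin(con, info$what, n = n, size = info$size,
                   signed = info$signed, endian = "little")
  } else {
    rawpath <- file.path(dirname(path), data_file)
    if (!file.exists(rawpath))
      stop("read_volume: MetaImage data file not found: ", rawpath)
    rcon <- file(rawpath, "rb"); on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, info$what, n = n, size = info$size,
                   signed = info$signed, endian = "little")
  }
  if (length(raw) != n)
    stop("read_volume: MetaImage data shorter than DimSize in ", path)
  list(data = array(raw, dims), spacing = spacing, origin = origin,
       integer_coded = info$int)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a volume to isotropic spacing
#'
#' Resamples onto an isotropic grid preserving the physical extent to within
#' one voxel. Scalar volumes use trilinear interpolation (`mode = "linear"`);
#' label volumes require nearest-neighbour (`mode = "nearest"`), which can
#' never introduce label values absent from the input.
#'
#' @param vol A [volume3d()] or [label_volume()].
#' @param target_spacing Isotropic target voxel size in mm (default 1).
#' @param mode `"linear"` or `"nearest"`; defaults to `"nearest"` for label
#'   volumes and `"linear"` otherwise.
#' @return A volume of the same class on the new grid.
#' @export
resample_isotropic <- function(vol, target_spacing = 1,
                               mode = if (is_label(vol)) "nearest" else "linear") {
  stopifnot(inherits(vol, "volume3d"))
  mode <- match.arg(mode, c("linear", "nearest"))
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      target_spacing <= 0)
    stop("resample_isotropic: target_spacing must be a single positive value")
  if (is_label(vol) && mode == "linear")
    stop("resample_isotropic: linear interpolation is invalid for a label ",
         "volume; use mode = \"nearest\"")
  d <- dim(vol$data)
  new_d <- pmax(1L, as.integer(round(d * vol$spacing / target_spacing)))
  out <- resample_grid_cpp(array(as.double(vol$data), d), vol$spacing,
                           new_d, rep(target_spacing, 3), mode == "nearest")
  if (is_label(vol))
    label_volume(out, spacing = rep(target_spacing, 3), origin = vol$origin,
                 labels = vol$labels)
  else
    volume3d(out, spacing = rep(target_spacing, 3), origin = vol$origin)
}

#' Check that volumes share one grid
#'
#' All volumes in a case must live on one grid: equal dimensions, and spacing
#' and origin agreeing to within `tol` mm.
#'
#' @param ... Two or more volumes.
#' @param tol Tolerance in mm on spacing and origin (default 1e-3).
#' @return `TRUE` invisibly; otherwise an error naming the first mismatch.
#' @export
assert_same_grid <- function(..., tol = 1e-3) {
  vols <- list(...)
  if (length(vols) == 1L && is.list(vols[[1]]) && !inherits(vols[[1]], "volume3d"))
    vols <- vols[[1]]
  stopifnot(length(vols) >= 2L)
  ref <- vols[[1]]
  for (i in seq_along(vols)[-1]) {
    v <- vols[[i]]
    if (!identical(dim(ref$data), dim(v$data)))
      stop("assert_same_grid: dimension mismatch (",
           paste(dim(ref$data), collapse = "x"), " vs ",
           paste(dim(v$data), collapse = "x"), ")")
    if (max(abs(ref$spacing - v$spacing)) > tol)
      stop("assert_same_grid: spacing mismatch beyond ", tol, " mm")
    if (max(abs(ref$origin - v$origin)) > tol)
      stop("assert_same_grid: origin mismatch beyond ", tol, " mm")
  }
  invisible(TRUE)
}
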