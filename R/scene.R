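#' 3D scene: a scalar volume with voxel spacing
#'
#' A `scene` is the package's container for a 3D image: a numeric (or
#' logical, for masks) array together with its voxel spacing in mm. All
#' voxel indices in this package are 1-based `(x, y, z)` triples into the
#' array, matching R's array indexing.
#'
#' @param values 3D array of scalar intensities (Hounsfield units or 8-bit
#'   rescaled values), or a logical array for a segmentation mask.
#' @param spacing numeric length-3 vector `(sx, sy, sz)`, mm per voxel along
#'   each axis; all components must be positive.
#' @return An object of class `scene` with components `values`, `spacing`
#'   and `dim`.
#' @examples
#' sc <- scene(array(100, dim = c(4, 4, 4)), spacing = c(0.7, 0.7, 1))
#' sc$dim
#' @export
scene <- function(values, spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("scene must be 3D", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("spacing must be three positive numbers (mm/voxel)", call. = FALSE)
  structure(list(values = values, spacing = spacing, dim = dim(values)),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  kind <- if (is.logical(x$values)) "mask" else "scene"
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              kind, x$dim[1], x$dim[2], x$dim[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  v <- x$values
  if (is.logical(v)) {
    cat(sprintf("  foreground voxels: %d (%.2f%%)\n",
                sum(v), 100 * mean(v)))
  } else {
    cat(sprintf("  intensity range: [%g, %g]\n", min(v), max(v)))
  }
  invisible(x)
}

#' @export
dim.scene <- function(x) x$dim

is_scene <- function(x) inherits(x, "scene")

# Stop unless `idx` is a valid 1-based voxel index into `sc`.
check_index <- function(sc, idx, what = "seed") {
  idx <- as.integer(idx)
  if (length(idx) != 3L || anyNA(idx))
    stop(what, " must be an (x, y, z) integer triple", call. = FALSE)
  if (any(idx < 1L) || any(idx > sc$dim))
    stop(what, " lies outside the scene", call. = FALSE)
  idx
}

infer_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.(mhd|mha)$", lower)) return("metaimage")
  if (grepl("\\.raw$", lower)) return("raw")
  stop("cannot infer volume format from '", path,
       "'; pass format = \"nifti\", \"metaimage\" or \"raw\"", call. = FALSE)
}

#' Read a 3D volume with voxel spacing
#'
#' Supported formats: NIfTI (`.nii`/`.nii.gz`, via \pkg{RNifti}), MetaImage
#' (`.mhd` text header + `.raw` blob, or a single `.mha` with the blob
#' appended), and a raw little-endian blob with a YAML sidecar
#' (`<path>.yaml` giving `shape`, `spacing`, `dtype`). Spacing must be
#' present in the header/sidecar; it is never silently defaulted.
#'
#' @param path file to read.
#' @param format one of `"nifti"`, `"metaimage"`, `"raw"`; inferred from the
#'   file extension when `NULL`.
#' @return A [scene].
#' @seealso [write_scene()]
#' @export
read_scene <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- match.arg(format %||% infer_format(path),
                      c("nifti", "metaimage", "raw"))
  switch(format,
    nifti = read_scene_nifti(path),
    metaimage = read_scene_mhd(path),
    raw = read_scene_raw(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_scene_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("scene must be 3D", call. = FALSE)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(sp[1:3] <= 0))
    stop("NIfTI header of '", path, "' lacks a valid voxel spacing",
         call. = FALSE)
  scene(array(as.numeric(img), dim = d), spacing = sp[1:3])
}

# MetaImage: key = value text header; we read/write the subset the format
# requires (MET_* element types, 3D, local or appended raw data).
mhd_dtypes <- c(MET_UCHAR = "uchar", MET_SHORT = "short", MET_USHORT = "ushort",
                MET_INT = "int", MET_FLOAT = "float", MET_DOUBLE = "double")

read_scene_mhd <- function(path) {
  if (grepl("\\.mha$", tolower(path))) {
    # header and blob share the file; header ends at the ElementDataFile line
    con <- file(path, "rb")
    on.exit(close(con))
    hdr_lines <- character()
    repeat {
      line <- readLines(con, n = 1L, warn = FALSE)
      if (length(line) == 0L) stop("truncated .mha header: ", path, call. = FALSE)
      hdr_lines <- c(hdr_lines, line)
      if (grepl("^\\s*ElementDataFile", line)) break
    }
    hdr <- parse_mhd_header(hdr_lines, path)
    vals <- read_mhd_blob(con, hdr)
  } else {
    hdr_lines <- readLines(path, warn = FALSE)
    hdr <- parse_mhd_header(hdr_lines, path)
    blob_path <- file.path(dirname(path), hdr$datafile)
    if (!file.exists(blob_path))
      stop("MetaImage data file not found: ", blob_path, call. = FALSE)
    con <- file(blob_path, "rb")
    on.exit(close(con))
    vals <- read_mhd_blob(con, hdr)
  }
  scene(array(vals, dim = hdr$shape), spacing = hdr$spacing)
}

parse_mhd_header <- function(lines, path) {
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3L) m[2] else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m) == 3L) m[3] else NA_character_, "")
  get <- function(k) { i <- match(k, keys); if (is.na(i)) NULL else vals[i] }
  ndims <- as.integer(get("NDims") %||% NA)
  if (is.na(ndims) || ndims != 3L) stop("scene must be 3D: ", path, call. = FALSE)
  shape <- as.integer(strsplit(get("DimSize") %||% "", "\\s+")[[1]])
  sp_raw <- get("ElementSpacing") %||% get("ElementSize")
  if (is.null(sp_raw))
    stop("MetaImage header of '", path, "' lacks ElementSpacing", call. = FALSE)
  spacing <- as.numeric(strsplit(sp_raw, "\\s+")[[1]])
  etype <- get("ElementType") %||% "MET_DOUBLE"
  dtype <- mhd_dtypes[[etype]] %||% stop("unsupported ElementType: ", etype,
                                         call. = FALSE)
  if (length(shape) != 3L || length(spacing) != 3L)
    stop("malformed MetaImage header: ", path, call. = FALSE)
  list(shape = shape, spacing = spacing, dtype = dtype,
       datafile = get("ElementDataFile") %||% "LOCAL")
}

dtype_info <- function(dtype) {
  switch(dtype,
    uchar  = list(what = "integer", size = 1L, signed = FALSE),
    short  = list(what = "integer", size = 2L, signed = TRUE),
    ushort = list(what = "integer", size = 2L, signed = FALSE),
    int    = list(what = "integer", size = 4L, signed = TRUE),
    float  = list(what = "numeric", size = 4L, signed = TRUE),
    double = list(what = "numeric", size = 8L, signed = TRUE),
    stop("unsupported dtype: ", dtype, call. = FALSE))
}

read_mhd_blob <- function(con, hdr) {
  info <- dtype_info(hdr$dtype)
  n <- prod(hdr$shape)
  vals <- readBin(con, what = info$what, n = n, size = info$size,
                  signed = info$signed, endian = "little")
  if (length(vals) != n)
    stop("MetaImage data shorter than DimSize promises", call. = FALSE)
  as.numeric(vals)
}

read_scene_raw <- function(path) {
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar))
    stop("raw volume needs a sidecar '", sidecar,
         "' with shape/spacing/dtype", call. = FALSE)
  meta <- yaml::read_yaml(sidecar)
  for (k in c("shape", "spacing", "dtype"))
    if (is.null(meta[[k]]))
      stop("sidecar '", sidecar, "' lacks field '", k, "'", call. = FALSE)
  shape <- as.integer(unlist(meta$shape))
  if (length(shape) != 3L) stop("scene must be 3D", call. = FALSE)
  info <- dtype_info(meta$dtype)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = info$what, n = prod(shape), size = info$size,
                  signed = info$signed, endian = "little")
  if (length(vals) != prod(shape))
    stop("raw volume shorter than sidecar shape promises", call. = FALSE)
  scene(array(as.numeric(vals), dim = shape),
        spacing = as.numeric(unlist(meta$spacing)))
}

#' Write a 3D volume
#'
#' Writes a [scene] (or mask) so that [read_scene()] recovers values, shape
#' and spacing exactly. Masks (logical values) are stored as uint8 0/1.
#' Integer-valued scenes within 0..255 are stored as uint8, other integer
#' scenes as int32, everything else as float64.
#'
#' @param sc a [scene] or a logical-valued mask scene.
#' @param path output file; for `format = "raw"` a `<path>.yaml` sidecar is
#'   written alongside.
#' @param format `"nifti"`, `"metaimage"` or `"raw"`; inferred from the
#'   extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_scene <- function(sc, path, format = NULL) {
  stopifnot(is_scene(sc))
  format <- match.arg(format %||% infer_format(path),
                      c("nifti", "metaimage", "raw"))
  dtype <- choose_dtype(sc$values)
  v <- sc$values
  if (is.logical(v)) v <- array(as.integer(v), dim = dim(v))
  ok <- switch(format,
    nifti = write_scene_nifti(v, sc$spacing, path, dtype),
    metaimage = write_scene_mhd(v, sc$spacing, path, dtype),
    raw = write_scene_raw(v, sc$spacing, path, dtype))
  invisible(path)
}

choose_dtype <- function(v) {
  if (is.logical(v)) return("uchar")
  if (all(v == round(v))) {
    if (min(v) >= 0 && max(v) <= 255) return("uchar")
    if (min(v) >= -2^31 && max(v) < 2^31) return("int")
  }
  "double"
}

write_scene_nifti <- function(v, spacing, path, dtype) {
  datatype <- switch(dtype, uchar = "uint8", int = "int32", "double")
  attr(v, "pixdim") <- spacing
  img <- RNifti::asNifti(v, datatype = datatype)
  RNifti::writeNifti(img, path)
}

write_scene_mhd <- function(v, spacing, path, dtype) {
  etype <- names(mhd_dtypes)[match(dtype, mhd_dtypes)]
  local <- grepl("\\.mha$", tolower(path))
  blob_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           sprintf("DimSize = %d %d %d", dim(v)[1], dim(v)[2], dim(v)[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g",
                   spacing[1], spacing[2], spacing[3]),
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("ElementType = %s", etype),
           sprintf("ElementDataFile = %s", if (local) "LOCAL" else blob_name))
  info <- dtype_info(dtype)
  write_blob <- function(con) {
    vals <- as.vector(v)
    if (info$what == "integer") vals <- as.integer(vals)
    writeBin(vals, con, size = info$size, endian = "little")
  }
  if (local) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    write_blob(con)
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), blob_name), "wb")
    on.exit(close(con))
    write_blob(con)
  }
  TRUE
}

write_scene_raw <- function(v, spacing, path, dtype) {
  info <- dtype_info(dtype)
  con <- file(path, "wb")
  on.exit(close(con))
  vals <- as.vector(v)
  if (info$what == "integer") vals <- as.integer(vals)
  writeBin(vals, con, size = info$size, endian = "little")
  yaml::write_yaml(list(shape = as.integer(dim(v)),
                        spacing = as.numeric(spacing),
                        dtype = dtype, byte_order = "little"),
                   paste0(path, ".yaml"))
  TRUE
}

#' Window a CT scene to the 8-bit range
#'
#' Linearly maps intensities in `[lo, hi]` (HU) onto 0..255, clamping values
#' outside the window and rounding half-up to the nearest integer. The
#' propagation core and its affinity lookup table assume 8-bit scenes, so CT
#' volumes in HU must pass through this map first; the default window
#' `[-100, 400]` brackets the contrast-enhanced vessel range (roughly
#' 100-230 after windowing) with parenchyma context.
#'
#' @param sc a [scene] in HU (or any scale).
#' @param lo,hi window bounds, `lo < hi`.
#' @return A [scene] with integer values in 0..255 and unchanged spacing.
#' @export
window_to_byte <- function(sc, lo = -100, hi = 400) {
  stopifnot(is_scene(sc))
  if (!(lo < hi)) stop("window requires lo < hi", call. = FALSE)
  x <- (sc$values - lo) / (hi - lo) * 255
  x <- pmin(pmax(x, 0), 255)
  scene(array(floor(x + 0.5), dim = sc$dim), spacing = sc$spacing)
}
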