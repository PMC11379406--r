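#' @useDynLib cryocontrast, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- format inference -------------------------------------------------------

infer_format <- function(path, format_hint = NULL) {
  if (!is.null(format_hint)) {
    format_hint <- match.arg(format_hint, c("nrrd", "nifti", "tiff_stack"))
    return(format_hint)
  }
  if (dir.exists(path)) return("tiff_stack")
  low <- tolower(path)
  if (grepl("\\.(nrrd|nhdr)$", low)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(tif|tiff)$", low)) return("tiff_stack")
  stop(sprintf("cannot infer volume format from '%s'; pass format_hint", path),
       call. = FALSE)
}

# ---- NRRD -------------------------------------------------------------------
# Minimal NRRD reader/writer (attached or detached header; raw, gzip or
# ascii encodings; scalar 3D data).  Sizes/spacings are listed fastest
# axis first, which for column-major R arrays is the first dimension (z).

nrrd_types <- list(
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "uint8_t" = list(what = "integer", size = 1, signed = FALSE),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "int32" = list(what = "integer", size = 4, signed = TRUE),
  "float" = list(what = "double", size = 4, signed = TRUE),
  "double" = list(what = "double", size = 8, signed = TRUE)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic))
    stop(sprintf("'%s' is not an NRRD file", path), call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) break          # EOF: detached headers allow this
    if (line == "") break                  # blank line ends attached header
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+): ?(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  need <- c("type", "dimension", "sizes", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss))
    stop(sprintf("NRRD header missing field(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (as.integer(fields$dimension) != 3L)
    stop("only 3-dimensional NRRD volumes are supported", call. = FALSE)
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  spacing <- NULL
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    # diagonal space directions: (a,0,0) (0,b,0) (0,0,c)
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    mat <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    offdiag <- mat; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-9))
      stop("non-axis-aligned NRRD space directions are not supported",
           call. = FALSE)
    spacing <- abs(diag(mat))
  }
  if (is.null(spacing))
    stop(sprintf("NRRD '%s' has no spacings/space directions; voxel spacing in mm is required",
                 path), call. = FALSE)
  ti <- nrrd_types[[tolower(fields$type)]]
  if (is.null(ti))
    stop(sprintf("unsupported NRRD type '%s'", fields$type), call. = FALSE)
  endian <- if (!is.null(fields$endian)) fields$endian else "little"
  n <- prod(sizes)
  enc <- tolower(fields$encoding)

  if (!is.null(fields[["data file"]])) {
    datapath <- file.path(dirname(path), fields[["data file"]])
    if (!file.exists(datapath))
      stop(sprintf("NRRD detached data file '%s' not found", datapath),
           call. = FALSE)
    payload <- readBin(datapath, "raw", n = file.info(datapath)$size)
  } else {
    sz <- file.info(path)$size
    pos <- seek(con, where = NA)
    payload <- readBin(con, "raw", n = sz - pos)
  }

  vals <- switch(enc,
    raw = readBin(payload, ti$what, n = n, size = ti$size,
                  signed = ti$signed, endian = endian),
    gzip = , gz = readBin(memDecompress(payload, type = "gzip"),
                          ti$what, n = n, size = ti$size,
                          signed = ti$signed, endian = endian),
    ascii = , text = , txt = scan(text = rawToChar(payload), what = double(),
                                  quiet = TRUE),
    stop(sprintf("unsupported NRRD encoding '%s'", enc), call. = FALSE)
  )
  if (length(vals) < n)
    stop(sprintf("NRRD '%s': expected %d values, got %d", path, n, length(vals)),
         call. = FALSE)
  list(data = array(as.double(vals[seq_len(n)]), dim = sizes),
       spacing = spacing)
}

write_nrrd <- function(data, spacing, path, type = "double",
                       encoding = "raw") {
  sizes <- dim(data)
  hdr <- c("NRRD0004",
           "# written by cryocontrast",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %d %d %d", sizes[1], sizes[2], sizes[3]),
           sprintf("spacings: %.17g %.17g %.17g",
                   spacing[1], spacing[2], spacing[3]),
           sprintf("encoding: %s", encoding))
  if (encoding == "raw") hdr <- c(hdr, "endian: little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(paste(format(as.vector(data), digits = 17, scientific = TRUE,
                            trim = TRUE), collapse = " "), con)
  } else {
    ti <- nrrd_types[[type]]
    vals <- as.vector(data)
    if (ti$what == "integer") vals <- as.integer(round(vals))
    writeBin(vals, con, size = ti$size, endian = "little")
  }
  invisible(NULL)
}

# ---- NIfTI ------------------------------------------------------------------
# RNifti indexes arrays (x, y, z); the package convention is (z, y, x).

read_nifti_vol <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop(sprintf("NIfTI '%s' is not a 3D scalar volume", path), call. = FALSE)
  sp <- RNifti::pixdim(im)[1:3]
  list(data = aperm(arr, c(3, 2, 1)), spacing = rev(sp))
}

write_nifti_vol <- function(data, spacing, path, datatype = "double") {
  arr <- aperm(data, c(3, 2, 1))
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- rev(spacing)
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(NULL)
}

# ---- TIFF stacks ------------------------------------------------------------
# A directory of numbered single-channel 2D TIFFs (one per z slice, each
# (y, x)) plus a YAML sidecar `spacing.yaml` giving spacing (and the
# intensity scale used for storage: slices hold (v - min)/(max - min) as
# 32-bit fixed point, exact to ~2^-32 of the data range).

read_tiff_stack <- function(path) {
  if (!dir.exists(path))
    stop(sprintf("TIFF stack path '%s' is not a directory", path),
         call. = FALSE)
  sidecar <- file.path(path, "spacing.yaml")
  if (!file.exists(sidecar))
    stop(sprintf(
      "TIFF stack '%s' has no spacing.yaml sidecar; voxel spacing in mm must be supplied",
      path), call. = FALSE)
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$spacing_mm) || length(meta$spacing_mm) != 3L)
    stop("spacing.yaml must contain `spacing_mm: [z, y, x]`", call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.(tif|tiff)$", full.names = TRUE))
  if (length(files) == 0L)
    stop(sprintf("no TIFF slices found in '%s'", path), call. = FALSE)
  slices <- lapply(files, tiff::readTIFF)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF slices have inconsistent dimensions", call. = FALSE)
  arr <- array(0, dim = c(length(slices), dims[1, 1], dims[2, 1]))
  for (z in seq_along(slices)) arr[z, , ] <- slices[[z]]
  lo <- if (!is.null(meta$intensity_min)) meta$intensity_min else 0
  hi <- if (!is.null(meta$intensity_max)) meta$intensity_max else 1
  list(data = arr * (hi - lo) + lo,
       spacing = as.numeric(meta$spacing_mm))
}

write_tiff_stack <- function(data, spacing, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, showWarnings = FALSE)
    if (!ok)
      stop(sprintf("cannot create TIFF stack directory '%s'", path),
           call. = FALSE)
  }
  lo <- min(data); hi <- max(data)
  scaled <- if (hi > lo) (data - lo) / (hi - lo) else array(0, dim = dim(data))
  nz <- dim(data)[1]
  for (z in seq_len(nz)) {
    tiff::writeTIFF(matrix(scaled[z, , ], dim(data)[2], dim(data)[3]),
                    file.path(path, sprintf("slice_%04d.tif", z)),
                    bits.per.sample = 32L)
  }
  yaml::write_yaml(list(spacing_mm = as.numeric(spacing),
                        intensity_min = lo, intensity_max = hi,
                        n_slices = nz),
                   file.path(path, "spacing.yaml"))
  invisible(NULL)
}

# ---- public API -------------------------------------------------------------

#' Read a 3D volume
#'
#' Reads an intensity volume from NRRD (attached or detached header; raw,
#' gzip or ascii encodings), NIfTI-1 (`.nii`/`.nii.gz`), or a directory
#' of numbered single-channel TIFF slices with a `spacing.yaml` sidecar.
#' Voxel spacing in mm is taken from the file metadata (NRRD `spacings`
#' or `space directions`, NIfTI `pixdim`, TIFF sidecar `spacing_mm`);
#' a volume without spacing is a configuration error, because every
#' downstream distance is in physical mm.
#'
#' @param path file (NRRD/NIfTI) or directory (TIFF stack).
#' @param format_hint optionally one of `"nrrd"`, `"nifti"`,
#'   `"tiff_stack"`; otherwise inferred from the extension.
#' @return A [volume3d()] in `(z, y, x)` order.
#' @export
read_volume <- function(path, format_hint = NULL) {
  fmt <- infer_format(path, format_hint)
  if (fmt != "tiff_stack" && !file.exists(path))
    stop(sprintf("volume file '%s' does not exist", path), call. = FALSE)
  raw <- switch(fmt,
                nrrd = read_nrrd(path),
                nifti = read_nifti_vol(path),
                tiff_stack = read_tiff_stack(path))
  n_bad <- sum(!is.finite(raw$data))
  if (n_bad > 0L)
    stop(sprintf("volume '%s' contains %d NaN/Inf voxel(s)", path, n_bad),
         call. = FALSE)
  volume3d(raw$data, raw$spacing)
}

#' Write a 3D volume
#'
#' Inverse of [read_volume()].  NRRD output is raw little-endian doubles
#' (bit-exact round trip); NIfTI output is float64; TIFF stacks store
#' min/max-scaled 32-bit fixed point with the scale in the sidecar.
#'
#' @param vol a [volume3d()].
#' @param path destination file (or directory for `tiff_stack`).
#' @param format one of `"nrrd"`, `"nifti"`, `"tiff_stack"`; inferred
#'   from the extension when `NULL`.
#' @export
write_volume <- function(vol, path, format = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  fmt <- infer_format(path, format)
  parent <- dirname(path)
  if (!dir.exists(parent))
    stop(sprintf("parent directory '%s' does not exist", parent),
         call. = FALSE)
  switch(fmt,
         nrrd = write_nrrd(vol$data, vol$spacing, path, type = "double"),
         nifti = write_nifti_vol(vol$data, vol$spacing, path),
         tiff_stack = write_tiff_stack(vol$data, vol$spacing, path))
  invisible(path)
}

#' Read a binary mask
#'
#' Masks are stored as 8-bit 0/1 volumes in the same formats as
#' intensity data; any strictly positive voxel is treated as set.
#'
#' @inheritParams read_volume
#' @param name region label for the returned mask.
#' @return A [label_mask()].
#' @export
read_mask <- function(path, name = "region", format_hint = NULL) {
  v <- read_volume(path, format_hint)
  label_mask(array(v$data > 0, dim = dim(v$data)), v$spacing, name = name)
}

#' Write a binary mask
#'
#' @param mask a [label_mask()].
#' @inheritParams write_volume
#' @export
write_mask <- function(mask, path, format = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  fmt <- infer_format(path, format)
  parent <- dirname(path)
  if (!dir.exists(parent))
    stop(sprintf("parent directory '%s' does not exist", parent),
         call. = FALSE)
  data <- array(as.double(mask$data), dim = dim(mask$data))
  switch(fmt,
         nrrd = write_nrrd(data, mask$spacing, path, type = "uint8"),
         nifti = write_nifti_vol(data, mask$spacing, path, datatype = "uint8"),
         tiff_stack = write_tiff_stack(data, mask$spacing, path))
  invisible(path)
}

#' Write a multi-label shell volume
#'
#' Exports a [shell_decomposition()] as a single integer-labelled volume
#' (shell k gets label k; background 0) for visual inspection in any
#' NRRD/NIfTI viewer.
#'
#' @param shells a shell decomposition from [inward_shells()] or
#'   [outward_shells()].
#' @param path destination file.
#' @param format as in [write_volume()].
#' @export
write_shell_labels <- function(shells, path, format = NULL) {
  stopifnot(inherits(shells, "shell_decomposition"))
  dims <- dim(shells$shells[[1]]$data)
  lab <- array(0, dim = dims)
  for (k in seq_along(shells$shells))
    lab[shells$shells[[k]]$data] <- k
  fmt <- infer_format(path, format)
  switch(fmt,
         nrrd = write_nrrd(lab, shells$shells[[1]]$spacing, path,
                           type = "int16"),
         nifti = write_nifti_vol(lab, shells$shells[[1]]$spacing, path,
                                 datatype = "int16"),
         tiff_stack = write_tiff_stack(lab, shells$shells[[1]]$spacing, path))
  invisible(path)
}
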