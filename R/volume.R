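#' 3D intensity volume
#'
#' The carrier of one fluorescence channel: a 3D array of finite,
#' non-negative intensities (arbitrary fluorescence units) together with
#' the physical voxel spacing in mm along each axis.  Arrays are stored in
#' `(z, y, x)` order, matching slice-stack acquisition: the first array
#' dimension is the slice axis.  All mm-valued parameters elsewhere in the
#' package are interpreted per axis in this order.
#'
#' @param data numeric 3D array, `(z, y, x)` order.
#' @param spacing numeric length-3, mm per voxel along `(z, y, x)`.
#' @return An object of class `volume3d` with fields `data`, `spacing`
#'   and `axis_order` (always `"zyx"`).
#' @examples
#' v <- volume3d(array(runif(27), dim = c(3, 3, 3)), spacing = c(1, 1, 1))
#' dim(v$data)
#' @export
volume3d <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume3d: `data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("volume3d: all three dimensions must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume3d: `spacing` must be 3 positive finite values (mm)",
         call. = FALSE)
  storage.mode(data) <- "double"
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop(sprintf("volume3d: %d voxel(s) are NaN/Inf", n_bad), call. = FALSE)
  structure(list(data = data, spacing = spacing, axis_order = "zyx"),
            class = "volume3d")
}

#' Binary region mask
#'
#' A 3D boolean region (tumor, brain, ventricles, reference, ...) on the
#' same `(z, y, x)` grid as the intensity volumes it is applied to.
#'
#' @param data logical (or coercible 0/1 numeric) 3D array.
#' @param spacing mm per voxel along `(z, y, x)`.
#' @param name region label, e.g. `"tumor"`.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, spacing, name = "region") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("label_mask: `data` must be a 3D array", call. = FALSE)
  if (is.numeric(data)) {
    if (any(!is.finite(data)) || !all(data %in% c(0, 1)))
      stop("label_mask: numeric mask data must be 0/1", call. = FALSE)
    data <- array(data > 0, dim = dim(data))
  }
  if (!is.logical(data))
    stop("label_mask: `data` must be logical or 0/1 numeric", call. = FALSE)
  if (anyNA(data))
    stop("label_mask: mask contains NA", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("label_mask: `spacing` must be 3 positive finite values (mm)",
         call. = FALSE)
  structure(list(data = data, spacing = spacing, name = as.character(name)[1],
                 axis_order = "zyx"),
            class = "label_mask")
}

#' Number of voxels set in a mask
#' @param mask a [label_mask()].
#' @return integer count.
#' @export
mask_count <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  sum(mask$data)
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d (z,y,x), spacing %s mm, range [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 6), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_mask '%s'> %d x %d x %d (z,y,x), spacing %s mm, %d voxels set\n",
              x$name, d[1], d[2], d[3],
              paste(signif(x$spacing, 6), collapse = " x "), sum(x$data)))
  invisible(x)
}

#' Enforce grid compatibility across channels and masks
#'
#' The analysis assumes all channels and masks are intrinsically
#' co-registered on one grid (as block-face cryo-imaging channels are).
#' No resampling is ever performed; a mismatched grid is a hard error.
#'
#' @param vols list of [volume3d()] / [label_mask()] objects.
#' @return Invisibly `TRUE` iff all shapes are equal and all spacings
#'   agree within 1e-6 mm; otherwise an error naming the first offending
#'   pair and axis.
#' @export
assert_coregistered <- function(vols) {
  if (!is.list(vols) || length(vols) == 0L)
    stop("assert_coregistered: need a non-empty list of volumes/masks",
         call. = FALSE)
  ok <- vapply(vols, function(v) inherits(v, c("volume3d", "label_mask")),
               logical(1))
  if (!all(ok))
    stop("assert_coregistered: all elements must be volume3d or label_mask",
         call. = FALSE)
  nm <- names(vols)
  if (is.null(nm)) nm <- rep("", length(vols))
  nm <- ifelse(nzchar(nm), nm, paste0("item ", seq_along(vols)))
  ref_dim <- dim(vols[[1]]$data)
  ref_sp <- vols[[1]]$spacing
  for (i in seq_along(vols)[-1]) {
    di <- dim(vols[[i]]$data)
    for (ax in 1:3) {
      if (di[ax] != ref_dim[ax])
        stop(sprintf(
          "assert_coregistered: shape mismatch between '%s' and '%s' on axis %d (%s): %d vs %d",
          nm[1], nm[i], ax, c("z", "y", "x")[ax], ref_dim[ax], di[ax]),
          call. = FALSE)
    }
    for (ax in 1:3) {
      if (abs(vols[[i]]$spacing[ax] - ref_sp[ax]) > 1e-6)
        stop(sprintf(
          "assert_coregistered: spacing mismatch between '%s' and '%s' on axis %d (%s): %.9g vs %.9g mm",
          nm[1], nm[i], ax, c("z", "y", "x")[ax], ref_sp[ax],
          vols[[i]]$spacing[ax]),
          call. = FALSE)
    }
  }
  invisible(TRUE)
}
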