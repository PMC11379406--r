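#' Signed boundary distance field of a mask
#'
#' Computes, for every voxel, the Euclidean distance in mm to the mask
#' boundary: `d_in` is positive exactly on mask voxels and holds the
#' center-to-center distance to the nearest background voxel; `d_out` is
#' the symmetric quantity for background voxels (distance to the nearest
#' mask voxel).  Distances respect anisotropic voxel spacing, so a one-
#' voxel step along an axis with 2 mm spacing counts 2 mm.  This field is
#' the substrate for all shell, margin and boundary-band constructions:
#' banding a distance field in mm is well defined regardless of voxel
#' anisotropy, unlike literal iterated binary erosion.
#'
#' @param mask a non-empty, non-full [label_mask()].
#' @return An object of class `boundary_distance_field` with fields
#'   `d_in`, `d_out` (3D arrays, mm) and `spacing`.
#' @export
boundary_distance <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  m <- mask$data
  n_set <- sum(m)
  if (n_set == 0L)
    stop("boundary_distance: mask is empty", call. = FALSE)
  if (n_set == length(m))
    stop("boundary_distance: mask covers the full grid; no boundary exists",
         call. = FALSE)
  dims <- dim(m)
  # d_in: distance from inside voxels to nearest background voxel center
  d_in_sq <- .edt_sq(as.vector(!m), as.integer(dims), mask$spacing)
  d_in <- array(sqrt(d_in_sq), dim = dims)
  d_in[!m] <- 0
  # d_out: distance from background voxels to nearest mask voxel center
  d_out_sq <- .edt_sq(as.vector(m), as.integer(dims), mask$spacing)
  d_out <- array(sqrt(d_out_sq), dim = dims)
  d_out[m] <- 0
  structure(list(d_in = d_in, d_out = d_out, spacing = mask$spacing),
            class = "boundary_distance_field")
}

new_shell_decomposition <- function(shells, direction, thickness_mm,
                                    source_mask) {
  structure(list(shells = shells, direction = direction,
                 thickness_mm = thickness_mm, source_mask = source_mask),
            class = "shell_decomposition")
}

#' @export
print.shell_decomposition <- function(x, ...) {
  cat(sprintf("<shell_decomposition> %s, %g mm pitch, %d shell(s): %s voxels\n",
              x$direction, x$thickness_mm, length(x$shells),
              paste(vapply(x$shells, function(s) sum(s$data), numeric(1)),
                    collapse = "/")))
  invisible(x)
}

#' Concentric shells moving inward from the mask boundary
#'
#' Decomposes the mask into disjoint concentric shells of fixed physical
#' thickness: shell k contains the voxels with
#' `(k-1)*thickness < d_in <= k*thickness`.  On an isotropic grid with
#' thickness equal to the spacing this reproduces the layers peeled off
#' by iterated binary erosion with the Euclidean unit-ball (face-
#' neighbor) structuring element.  Construction stops at the last
#' non-empty shell, so the union of shells is exactly the input mask.
#'
#' @param mask a non-empty [label_mask()].
#' @param thickness_mm shell pitch in mm (default 1).
#' @return A `shell_decomposition` with `direction = "inward"`.
#' @export
inward_shells <- function(mask, thickness_mm = 1.0) {
  stopifnot(inherits(mask, "label_mask"))
  if (!is.numeric(thickness_mm) || length(thickness_mm) != 1L ||
      !is.finite(thickness_mm) || thickness_mm <= 0)
    stop("inward_shells: thickness_mm must be a positive number",
         call. = FALSE)
  if (sum(mask$data) == 0L)
    stop("inward_shells: mask is empty", call. = FALSE)
  bd <- boundary_distance(mask)
  d <- bd$d_in
  kmax <- ceiling(max(d) / thickness_mm)
  shells <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    sel <- d > (k - 1) * thickness_mm & d <= k * thickness_mm
    shells[[k]] <- label_mask(array(sel, dim = dim(d)), mask$spacing,
                              name = sprintf("%s_in_shell_%d", mask$name, k))
  }
  nonempty <- vapply(shells, function(s) sum(s$data) > 0L, logical(1))
  last <- if (any(nonempty)) max(which(nonempty)) else 0L
  # stop at the first empty shell; beyond max(d) all are empty anyway
  first_empty <- which(!nonempty)
  if (length(first_empty) > 0L) last <- min(last, min(first_empty) - 1L)
  new_shell_decomposition(shells[seq_len(last)], "inward", thickness_mm, mask)
}

#' Concentric shells moving outward from the mask boundary
#'
#' Shell k contains the background voxels with
#' `(k-1)*thickness < d_out <= k*thickness`, optionally intersected with
#' a limiting mask (typically the brain, so peritumoral shells stay in
#' tissue rather than running into the embedding medium).  Shells are
#' clipped at the grid boundary and may number fewer than `n_shells`
#' when the domain is exhausted.
#'
#' @param mask a non-empty [label_mask()] (e.g. the tumor).
#' @param thickness_mm shell pitch in mm (default 1).
#' @param n_shells number of outward shells requested.
#' @param limit_mask optional [label_mask()] to intersect each shell with.
#' @return A `shell_decomposition` with `direction = "outward"`.
#' @export
outward_shells <- function(mask, thickness_mm = 1.0, n_shells = 1L,
                           limit_mask = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  if (!is.numeric(thickness_mm) || length(thickness_mm) != 1L ||
      !is.finite(thickness_mm) || thickness_mm <= 0)
    stop("outward_shells: thickness_mm must be a positive number",
         call. = FALSE)
  if (n_shells < 1L)
    stop("outward_shells: n_shells must be >= 1", call. = FALSE)
  if (sum(mask$data) == 0L)
    stop("outward_shells: mask is empty", call. = FALSE)
  if (!is.null(limit_mask)) {
    stopifnot(inherits(limit_mask, "label_mask"))
    assert_coregistered(list(mask = mask, limit = limit_mask))
  }
  bd <- boundary_distance(mask)
  d <- bd$d_out
  shells <- list()
  for (k in seq_len(n_shells)) {
    sel <- d > (k - 1) * thickness_mm & d <= k * thickness_mm
    if (!is.null(limit_mask)) sel <- sel & limit_mask$data
    if (!any(sel)) break
    shells[[length(shells) + 1L]] <-
      label_mask(array(sel, dim = dim(d)), mask$spacing,
                 name = sprintf("%s_out_shell_%d", mask$name, k))
  }
  if (length(shells) == 0L)
    warning("outward_shells: no non-empty shells (domain exhausted)",
            call. = FALSE)
  new_shell_decomposition(shells, "outward", thickness_mm, mask)
}

#' 1 mm margin regions on either side of the mask boundary
#'
#' The two regions used for margin-restricted contrast metrics: the
#' outermost 1 mm of the tumor (first inward shell) and the adjacent
#' 1 mm peritumoral rind (first outward shell, intersected with the
#' brain mask when supplied).
#'
#' @param mask tumor [label_mask()].
#' @param limit_mask optional brain [label_mask()] restricting the outer
#'   margin to tissue.
#' @param thickness_mm margin width in mm (default 1).
#' @return list with `inner_1mm` and `outer_1mm` [label_mask()]s.
#' @export
margin_regions <- function(mask, limit_mask = NULL, thickness_mm = 1.0) {
  inner <- inward_shells(mask, thickness_mm)$shells[[1]]
  outer_dec <- outward_shells(mask, thickness_mm, n_shells = 1L,
                              limit_mask = limit_mask)
  if (length(outer_dec$shells) == 0L)
    stop("margin_regions: outer margin is empty", call. = FALSE)
  outer <- outer_dec$shells[[1]]
  inner$name <- paste0(mask$name, "_inner_1mm")
  outer$name <- paste0(mask$name, "_outer_1mm")
  list(inner_1mm = inner, outer_1mm = outer)
}

#' Boundary band spanning the mask surface
#'
#' All voxels within `half_width_mm` of the mask boundary on either
#' side: `{inside: d_in <= h} U {outside: d_out <= h}`.  With
#' `half_width_mm = 1` this is the 2 mm thick volume spanning the tumor
#' boundary used for the band-restricted cross-correlation.
#'
#' @param mask a non-empty [label_mask()].
#' @param half_width_mm band half-width in mm (default 1).
#' @param limit_mask optional [label_mask()] intersected with the outside
#'   part of the band.
#' @return A [label_mask()].
#' @export
boundary_band <- function(mask, half_width_mm = 1.0, limit_mask = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  if (!is.numeric(half_width_mm) || length(half_width_mm) != 1L ||
      !is.finite(half_width_mm) || half_width_mm <= 0)
    stop("boundary_band: half_width_mm must be a positive number",
         call. = FALSE)
  bd <- boundary_distance(mask)
  inside <- bd$d_in > 0 & bd$d_in <= half_width_mm
  outside <- bd$d_out > 0 & bd$d_out <= half_width_mm
  if (!is.null(limit_mask)) outside <- outside & limit_mask$data
  label_mask(array(inside | outside, dim = dim(bd$d_in)), mask$spacing,
             name = paste0(mask$name, "_band"))
}

#' Mirror a mask across a symmetry plane (contralateral region)
#'
#' Produces an equivalently sized normal-tissue reference region by
#' voxel-wise reflection of the mask across an axis-aligned plane
#' (typically the mid-sagittal plane).  The reflection maps voxel index
#' `i` to `2c - i` along the chosen axis; voxel count is preserved
#' exactly.  The mirrored region must lie inside the grid and must not
#' intersect the source mask (it is meant to be normal tissue).
#'
#' @param mask tumor [label_mask()].
#' @param axis symmetry plane normal: 1..3 or `"z"`,`"y"`,`"x"`.
#' @param coordinate plane position as a (possibly half-integer) voxel
#'   index `c`; `2c` must be an integer so reflected indices land on the
#'   grid.
#' @return The mirrored [label_mask()].
#' @export
contralateral_region <- function(mask, axis, coordinate) {
  stopifnot(inherits(mask, "label_mask"))
  if (is.character(axis))
    axis <- match(match.arg(axis, c("z", "y", "x")), c("z", "y", "x"))
  axis <- as.integer(axis)
  if (!axis %in% 1:3)
    stop("contralateral_region: axis must be 1..3 or 'z'/'y'/'x'",
         call. = FALSE)
  if (abs(2 * coordinate - round(2 * coordinate)) > 1e-9)
    stop("contralateral_region: 2*coordinate must be an integer so reflected voxel indices are on the grid",
         call. = FALSE)
  if (sum(mask$data) == 0L)
    stop("contralateral_region: mask is empty", call. = FALSE)
  dims <- dim(mask$data)
  idx <- which(mask$data, arr.ind = TRUE)
  ref <- idx
  ref[, axis] <- round(2 * coordinate - idx[, axis])
  if (any(ref[, axis] < 1L) || any(ref[, axis] > dims[axis]))
    stop(sprintf(
      "contralateral_region: reflection across axis %d at %.1f exits the grid",
      axis, coordinate), call. = FALSE)
  out <- array(FALSE, dim = dims)
  out[ref] <- TRUE
  if (any(out & mask$data))
    stop("contralateral_region: mirrored region overlaps the source mask; the reference must be normal tissue",
         call. = FALSE)
  label_mask(out, mask$spacing, name = paste0(mask$name, "_contralateral"))
}
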