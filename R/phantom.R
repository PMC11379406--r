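#' Synthetic dual-agent brain phantom specification
#'
#' Describes a brain-shaped domain (ellipsoid) containing an ellipsoidal
#' tumor and optional capsule-shaped ventricles, with two noiseless
#' intensity models driven by the Euclidean distance to the tumor
#' boundary:
#'
#' * **channel A (rim-enhancing, PpIX-like)** peaks at the tumor
#'   boundary and decays toward the center, bottoming out at
#'   `center_fraction` of the peak (default 0.125, i.e. the rim is about
#'   eight times brighter than the core), with elevated peritumoral
#'   signal decaying exponentially into normal brain;
#' * **channel B (core-enhancing, ICG-like)** rises monotonically with
#'   depth into the tumor, `background + peak * (1 - exp(-d/decay))`;
#'   outside, the boundary-layer value decays into normal brain with the
#'   same peritumoral length.
#'
#' Ventricle voxels are multiplied by a per-channel gain; independent
#' Gaussian noise is added per voxel and negatives are clipped to zero.
#' All geometry is in physical mm, `(z, y, x)` order, with voxel i
#' centered at `(i - 0.5) * spacing`.
#'
#' @param grid_shape integer length-3 `(z, y, x)`.
#' @param spacing mm per voxel, length-3.
#' @param brain_center,brain_semiaxes ellipsoid of the brain domain (mm).
#' @param tumor_center,tumor_semiaxes tumor ellipsoid (mm), strictly
#'   inside the brain.
#' @param ventricle_segments list of capsules, each
#'   `list(p1 = mm3, p2 = mm3, radius = mm)`.
#' @param background_level length-2 `(A, B)` normal-brain mean intensity.
#' @param rim_peak,center_fraction,boundary_width_mm channel-A model:
#'   peak rim amplitude above background, core-to-rim fraction in
#'   (0, 1], rim decay length (mm).
#' @param core_peak,decay_length_mm channel-B model: asymptotic core
#'   amplitude above background and its rise length (mm).
#' @param peritumoral_decay_mm decay length (mm) of tumor-associated
#'   signal into normal brain.
#' @param ventricle_gain length-2 `(A, B)` multiplier (>= 1) on
#'   ventricle voxels.
#' @param noise_sd length-2 `(A, B)` additive Gaussian noise sd.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing = c(1, 1, 1),
                         brain_center = c(32, 32, 32),
                         brain_semiaxes = c(24, 28, 26),
                         tumor_center = c(32, 32, 44),
                         tumor_semiaxes = c(7, 8, 7),
                         ventricle_segments = list(
                           list(p1 = c(28, 24, 32), p2 = c(28, 40, 32),
                                radius = 1.5),
                           list(p1 = c(36, 24, 32), p2 = c(36, 40, 32),
                                radius = 1.5)),
                         background_level = c(A = 250, B = 150),
                         rim_peak = 5000,
                         center_fraction = 0.125,
                         boundary_width_mm = 1.5,
                         core_peak = 6000,
                         decay_length_mm = 3,
                         peritumoral_decay_mm = 2,
                         ventricle_gain = c(A = 1.6, B = 3),
                         noise_sd = c(A = 20, B = 20),
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing = as.numeric(spacing),
               brain_center = as.numeric(brain_center),
               brain_semiaxes = as.numeric(brain_semiaxes),
               tumor_center = as.numeric(tumor_center),
               tumor_semiaxes = as.numeric(tumor_semiaxes),
               ventricle_segments = ventricle_segments,
               background_level = stats::setNames(as.numeric(background_level),
                                                  c("A", "B")),
               rim_peak = as.numeric(rim_peak),
               center_fraction = as.numeric(center_fraction),
               boundary_width_mm = as.numeric(boundary_width_mm),
               core_peak = as.numeric(core_peak),
               decay_length_mm = as.numeric(decay_length_mm),
               peritumoral_decay_mm = as.numeric(peritumoral_decay_mm),
               ventricle_gain = stats::setNames(as.numeric(ventricle_gain),
                                                c("A", "B")),
               noise_sd = stats::setNames(as.numeric(noise_sd), c("A", "B")),
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
              length(spacing) == 3L, all(spacing > 0),
              length(background_level) == 2L, all(background_level >= 0),
              rim_peak >= 0, core_peak >= 0,
              center_fraction > 0, center_fraction <= 1,
              boundary_width_mm > 0, decay_length_mm > 0,
              peritumoral_decay_mm > 0,
              all(ventricle_gain >= 1), all(noise_sd >= 0))
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> grid %s, spacing %s mm, seed %d\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$seed))
  cat(sprintf("  rim agent: peak %g, center fraction %g, width %g mm\n",
              x$rim_peak, x$center_fraction, x$boundary_width_mm))
  cat(sprintf("  core agent: peak %g, rise length %g mm\n",
              x$core_peak, x$decay_length_mm))
  invisible(x)
}

# voxel-center physical coordinates along each axis
voxel_centers <- function(grid_shape, spacing) {
  lapply(1:3, function(a) (seq_len(grid_shape[a]) - 0.5) * spacing[a])
}

ellipsoid_mask <- function(grid_shape, spacing, center, semiaxes) {
  cc <- voxel_centers(grid_shape, spacing)
  tz <- ((cc[[1]] - center[1]) / semiaxes[1])^2
  ty <- ((cc[[2]] - center[2]) / semiaxes[2])^2
  tx <- ((cc[[3]] - center[3]) / semiaxes[3])^2
  q <- outer(outer(tz, ty, "+"), tx, "+")
  array(q <= 1, dim = grid_shape)
}

capsule_mask <- function(grid_shape, spacing, p1, p2, radius) {
  cc <- voxel_centers(grid_shape, spacing)
  g <- expand.grid(z = cc[[1]], y = cc[[2]], x = cc[[3]])
  p <- cbind(g$z, g$y, g$x)
  v <- p2 - p1
  len2 <- sum(v^2)
  if (len2 == 0) {
    d2 <- rowSums((p - matrix(p1, nrow(p), 3, byrow = TRUE))^2)
  } else {
    t <- pmin(pmax(((p[, 1] - p1[1]) * v[1] + (p[, 2] - p1[2]) * v[2] +
                      (p[, 3] - p1[3]) * v[3]) / len2, 0), 1)
    proj <- cbind(p1[1] + t * v[1], p1[2] + t * v[2], p1[3] + t * v[3])
    d2 <- rowSums((p - proj)^2)
  }
  array(d2 <= radius^2, dim = grid_shape)
}

# geometry + noiseless intensity model shared by the generator and the
# analytic ground-truth evaluator
phantom_fields <- function(spec) {
  gs <- spec$grid_shape
  sp <- spec$spacing
  brain <- ellipsoid_mask(gs, sp, spec$brain_center, spec$brain_semiaxes)
  tumor <- ellipsoid_mask(gs, sp, spec$tumor_center, spec$tumor_semiaxes)
  vent <- array(FALSE, dim = gs)
  for (seg in spec$ventricle_segments)
    vent <- vent | capsule_mask(gs, sp, seg$p1, seg$p2, seg$radius)
  vent <- vent & brain
  if (any(tumor & !brain))
    stop("phantom: tumor is not strictly inside the brain", call. = FALSE)
  # strictly inside: no tumor voxel may touch the brain boundary layer
  tumor_mask <- label_mask(tumor, sp, "tumor")
  brain_mask <- label_mask(brain, sp, "brain")
  bd_brain <- boundary_distance(brain_mask)
  if (any(tumor & bd_brain$d_in <= min(sp)))
    stop("phantom: tumor touches the brain boundary; it must be strictly inside",
         call. = FALSE)
  bd <- boundary_distance(tumor_mask)
  d_in <- bd$d_in
  d_out <- bd$d_out

  bA <- spec$background_level[["A"]]
  bB <- spec$background_level[["B"]]
  cf <- spec$center_fraction
  # channel A: rim-enhancing.  Continuity at the boundary: the inside
  # model tends to background + peak as d_in -> 0, so the outside decay
  # starts from the same value (continuity factor 1).
  A <- array(0, dim = gs)
  A[tumor] <- bA + spec$rim_peak *
    (cf + (1 - cf) * exp(-d_in[tumor] / spec$boundary_width_mm))
  outb <- brain & !tumor
  A[outb] <- bA + spec$rim_peak *
    exp(-d_out[outb] / spec$peritumoral_decay_mm)
  # channel B: core-enhancing inside; outside, tumor-associated signal
  # decays into normal brain from the boundary value.  The boundary value
  # is the inside model at the shallowest attainable voxel depth (the
  # voxel-center convention puts boundary voxels at d_in ~ spacing), so
  # the discrete field is continuous across the boundary layer.
  d0 <- min(sp)
  halo_B <- spec$core_peak * (1 - exp(-d0 / spec$decay_length_mm))
  B <- array(0, dim = gs)
  B[tumor] <- bB + spec$core_peak *
    (1 - exp(-d_in[tumor] / spec$decay_length_mm))
  B[outb] <- bB + halo_B * exp(-d_out[outb] / spec$peritumoral_decay_mm)
  # ventricles enhance in both channels
  A[vent] <- A[vent] * spec$ventricle_gain[["A"]]
  B[vent] <- B[vent] * spec$ventricle_gain[["B"]]

  list(A = A, B = B, tumor = tumor_mask, brain = brain_mask,
       ventricles = label_mask(vent, sp, "ventricles"),
       d_in = d_in, d_out = d_out)
}

#' Generate a synthetic dual-agent phantom
#'
#' Evaluates the noiseless intensity model of [phantom_spec()], applies
#' the ventricle gain, adds independent per-voxel Gaussian noise, clips
#' negatives to zero, and returns both channels with ground-truth masks.
#' The same spec and seed always produce bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list with `channel_A`, `channel_B` ([volume3d()]), and
#'   `tumor`, `brain`, `ventricles` ([label_mask()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  f <- phantom_fields(spec)
  gs <- spec$grid_shape
  n <- prod(gs)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)
  A <- f$A
  B <- f$B
  if (spec$noise_sd[["A"]] > 0)
    A <- A + array(stats::rnorm(n, 0, spec$noise_sd[["A"]]), dim = gs)
  if (spec$noise_sd[["B"]] > 0)
    B <- B + array(stats::rnorm(n, 0, spec$noise_sd[["B"]]), dim = gs)
  A[A < 0] <- 0
  B[B < 0] <- 0
  list(channel_A = volume3d(A, spec$spacing),
       channel_B = volume3d(B, spec$spacing),
       tumor = f$tumor, brain = f$brain, ventricles = f$ventricles)
}

#' Default symmetry plane of a phantom
#'
#' The mid-"sagittal" plane of the phantom brain: the plane normal to
#' the x axis through the brain ellipsoid center, expressed as a voxel
#' index usable by [contralateral_region()].
#'
#' @param spec a [phantom_spec()].
#' @return list with `axis` (3, the x axis) and `coordinate` (voxel
#'   index).
#' @export
phantom_symmetry_plane <- function(spec) {
  coord <- spec$brain_center[3] / spec$spacing[3] + 0.5
  if (abs(2 * coord - round(2 * coord)) > 1e-9)
    stop("phantom brain center does not fall on a half-voxel x position; supply the symmetry plane explicitly",
         call. = FALSE)
  list(axis = 3L, coordinate = coord)
}

#' Analytic (noise-free) region means of the phantom model
#'
#' Evaluates the noiseless intensity model directly on the grid and
#' averages it over one of the canonical analysis regions, providing
#' exact ground truth for parameter-recovery tests of the measurement
#' pipeline.
#'
#' @param spec a [phantom_spec()].
#' @param region one of `"tumor"`, `"margin_in_1mm"`, `"margin_out_1mm"`,
#'   `"contralateral"`.
#' @return Named numeric `(A, B)`: expected mean intensity per channel.
#' @export
analytic_region_means <- function(spec,
                                  region = c("tumor", "margin_in_1mm",
                                             "margin_out_1mm",
                                             "contralateral")) {
  stopifnot(inherits(spec, "phantom_spec"))
  region <- match.arg(region)
  f <- phantom_fields(spec)
  sel <- switch(region,
    tumor = f$tumor$data,
    margin_in_1mm = f$d_in > 0 & f$d_in <= 1,
    margin_out_1mm = f$d_out > 0 & f$d_out <= 1 & f$brain$data,
    contralateral = {
      pl <- phantom_symmetry_plane(spec)
      contralateral_region(f$tumor, pl$axis, pl$coordinate)$data
    })
  if (!any(sel))
    stop(sprintf("analytic_region_means: region '%s' is empty", region),
         call. = FALSE)
  c(A = mean(f$A[sel]), B = mean(f$B[sel]))
}

#' Write a phantom spec as YAML
#' @param spec a [phantom_spec()].
#' @param path destination file.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Read a phantom spec from YAML
#' @param path YAML file written by [write_phantom_spec()] or by hand.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(phantom_spec, raw[intersect(names(raw),
                                      names(formals(phantom_spec)))])
}
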