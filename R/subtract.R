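#' Spherical mask at a subunit position
#'
#' Builds a mask over one subunit: a sphere of the given diameter
#' centered at the endpoint of the subunit vector (Angstrom from the
#' map center), optionally with a soft cosine edge appended outside the
#' nominal radius.
#'
#' @param center A [subunit_vector()] locating the subunit center, or a
#'   numeric 3-vector in Angstrom from the map center (use `c(0,0,0)`
#'   for a centered sphere).
#' @param diameter Sphere diameter in Angstrom.
#' @param n Grid side length in pixels.
#' @param pixel_size Angstrom per pixel.
#' @param soft_edge Cosine edge width in pixels (0 for a binary mask).
#' @return A [density_map()] with voxel values in `[0, 1]`.
#' @export
make_spherical_mask <- function(center, diameter, n, pixel_size, soft_edge = 0) {
  stopifnot(diameter > 0)
  ctr <- if (inherits(center, "subunit_vector")) {
    center$direction * center$length
  } else {
    stopifnot(is.numeric(center), length(center) == 3)
    as.numeric(center)
  }
  ctr_px <- ctr / pixel_size
  r_px <- diameter / 2 / pixel_size
  if (any(abs(ctr_px) + r_px > n / 2)) {
    stop("mask sphere extends outside the grid", call. = FALSE)
  }
  ax <- seq_len(n) - 1 - n / 2
  dx <- ax - ctr_px[1]; dy <- ax - ctr_px[2]; dz <- ax - ctr_px[3]
  r <- sqrt(outer(outer(dx^2, dy^2, "+"), dz^2, "+"))
  m <- ifelse(r <= r_px, 1,
              if (soft_edge > 0) {
                ifelse(r <= r_px + soft_edge,
                       0.5 * (1 + cos(pi * (r - r_px) / soft_edge)), 0)
              } else 0)
  density_map(array(m, c(n, n, n)), pixel_size)
}

#' Apply a point-group symmetry to a mask
#'
#' Resamples the mask under every rotation of the group and takes the
#' voxelwise maximum, yielding the union of all symmetry-related
#' copies. Idempotent: symmetrizing twice equals once.
#'
#' @param mask A [density_map()] with values in `[0, 1]`.
#' @param sym A [point_group()] or symmetry label.
#' @return The symmetrized mask.
#' @export
symmetrize_mask <- function(mask, sym) {
  stopifnot(inherits(mask, "density_map"))
  if (is.character(sym)) sym <- point_group(sym)
  arr <- mask$data
  out <- arr
  for (g in sym$matrices) {
    if (max(abs(g - diag(3))) < 1e-12) next
    out <- pmax(out, .cpp_resample_rotated(arr, dim(arr), g))
  }
  out <- pmin(pmax(out, 0), 1)
  density_map(out, mask$pixel_size)
}

#' Flatten masked voxels to the background level
#'
#' Replaces the density inside the mask by the background level, giving
#' a map of everything *except* the masked subunits (the map that is
#' projected and subtracted from the particle images). The background
#' is the mean of unmasked voxels in the solvent region outside a
#' generous particle-radius sphere (or the global unmasked mean). Soft
#' mask values blend linearly.
#'
#' @param map A [density_map()].
#' @param mask A [density_map()] mask on the same grid, values in
#'   `[0, 1]`.
#' @param background `"solvent"` or `"global"`.
#' @param particle_radius Solvent boundary radius in pixels; defaults
#'   to `0.45 * n`.
#' @return The masked-to-background map.
#' @export
mask_to_background <- function(map, mask, background = c("solvent", "global"),
                               particle_radius = NULL) {
  background <- match.arg(background)
  stopifnot(inherits(map, "density_map"), inherits(mask, "density_map"))
  if (!all(dim(map$data) == dim(mask$data))) {
    stop("map and mask grids differ", call. = FALSE)
  }
  m <- mask$data
  unmasked <- m < 0.5
  if (!any(unmasked)) stop("mask covers the entire map", call. = FALSE)
  n <- dim(map$data)[1]
  sel <- if (background == "solvent") {
    if (is.null(particle_radius)) particle_radius <- 0.45 * n
    solvent <- radius_grid(dim(map$data)) > particle_radius
    if (any(solvent & unmasked)) solvent & unmasked else unmasked
  } else {
    unmasked
  }
  bg <- mean(map$data[sel])
  density_map(map$data * (1 - m) + bg * m, map$pixel_size)
}

#' Subtract the projected bulk density from particle images
#'
#' Projects the masked (subunit-free) reconstruction in each particle's
#' orientation and origin, modulates it by the particle's CTF, and
#' subtracts it from the particle image, leaving mostly subunit signal.
#' An optional least-squares intensity scale between the projection and
#' the image can be applied first for experimental data whose absolute
#' scale is arbitrary; it is off by default because the fit is biased
#' whenever the retained subunit signal correlates with the reference
#' projection. The whole-particle defocus is used for the subtraction
#' projection, since sub-particle heights vary across one image.
#'
#' @param image Numeric matrix (one particle image).
#' @param masked_map The bulk [density_map()] (subunits removed).
#' @param record One-row tibble with Euler angles, origins, CTF
#'   parameters and `pixel_size`, as from [as_particles()].
#' @param scale Apply the least-squares intensity scale.
#' @param projector Optional precomputed [fourier_projector()] of
#'   `masked_map` (built internally otherwise).
#' @return The subtracted image.
#' @export
subtract_projection <- function(image, masked_map, record, scale = FALSE,
                                projector = NULL) {
  if (is.null(projector)) {
    if (abs(masked_map$pixel_size - record$pixel_size[1]) > 1e-6) {
      stop("pixel size mismatch between map and particle record", call. = FALSE)
    }
    projector <- fourier_projector(masked_map)
  }
  ref <- project_slice(projector,
                       c(record$rot[1], record$tilt[1], record$psi[1]),
                       c(record$origin_x[1], record$origin_y[1]))
  ref <- apply_ctf(ref, record, projector$pixel_size, "full")
  if (scale) {
    denom <- sum(ref^2)
    k <- if (denom > 0) sum(image * ref) / denom else 0
    ref <- k * ref
  }
  image - ref
}

#' @rdname subtract_projection
#' @param images An [image_stack()] of particle images (slice `i` is
#'   `particle_id == i`).
#' @param records Particle records, one row per image.
#' @return `subtract_projections()` returns the subtracted
#'   [image_stack()].
#' @export
subtract_projections <- function(images, masked_map, records, scale = FALSE) {
  stopifnot(inherits(images, "image_stack"))
  if (abs(masked_map$pixel_size - images$pixel_size) > 1e-6) {
    stop("pixel size mismatch between map and images", call. = FALSE)
  }
  projector <- fourier_projector(masked_map)
  out <- images$data
  for (i in seq_len(nrow(records))) {
    id <- records$particle_id[i]
    out[, , id] <- subtract_projection(images$data[, , id], masked_map,
                                       records[i, ], scale = scale,
                                       projector = projector)
  }
  image_stack(out, images$pixel_size)
}
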