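#' Expand particles into sub-particle records by symmetry
#'
#' The core bookkeeping step of localized reconstruction. For every
#' particle, the subunit vector is rotated by each symmetry operator of
#' the point group; operators whose rotated positions coincide (within
#' `merge_tol` pixels) are merged into one symmetry-distinct *site*, so
#' a vector on an n-fold axis yields `order(G)/n` sites per particle
#' (orbit--stabilizer). The operators merged into one site differ only
#' by a rotation about the subunit axis: they are the *degenerate
#' orientations* of that site (e.g. 0/120/240 degrees on a threefold
#' axis). For each record the sub-particle pose is
#' `M_particle %*% M_sym %*% M_vec`, expressed as Euler angles; the
#' rotated vector gives the in-plane position (split into an integer
#' extraction coordinate and a sub-pixel origin) and the height along
#' the beam, which shifts the defocus.
#'
#' @param particles Tibble of particle records as from [as_particles()]
#'   (columns `particle_id`, `rot`, `tilt`, `psi`, `origin_x`,
#'   `origin_y`, `defocus_u`, `defocus_v`, `astig_angle`, `voltage`,
#'   `cs`, `amplitude_contrast`, `pixel_size`).
#' @param sym A [point_group()] or symmetry label string.
#' @param v A [subunit_vector()].
#' @param image_size Side length of the (pre-boxed) particle images in
#'   pixels; sub-particle coordinates are relative to these images.
#' @param merge_tol Coincident-position merge tolerance in pixels.
#' @param degenerate How to resolve the degenerate orientations of each
#'   site: `"random"` draws one uniformly (seeded, so the further
#'   processing is not biased), `"first"` always takes the canonical
#'   representative, `"all"` emits every one (one record per group
#'   element).
#' @param seed Integer seed for the `"random"` choice.
#' @param invert_defocus_z Flip the sign convention relating height
#'   along the beam to the defocus shift (see [adjust_defocus()]).
#' @return A tibble with one row per sub-particle: `parent_id`,
#'   `site_index` (0-based), `degen_index` (0-based), `n_degen`,
#'   Euler angles, `coord_x`, `coord_y` (integer extraction position,
#'   0-based pixels), `origin_x`, `origin_y` (sub-pixel origins in
#'   (-0.5, 0.5]), `center_x`, `center_y` (the exact sub-particle
#'   center), `z_height` (pixels, signed along the beam), `elevation`
#'   (degrees of the rotated vector above the image plane), and the
#'   CTF columns with height-adjusted defocus.
#' @export
expand_subparticles <- function(particles, sym, v, image_size,
                                merge_tol = 1, degenerate = c("random", "first", "all"),
                                seed = NULL, invert_defocus_z = FALSE) {
  degenerate <- match.arg(degenerate)
  stopifnot(inherits(v, "subunit_vector"), nrow(particles) > 0)
  if (is.character(sym)) sym <- point_group(sym)
  angpix <- unique(particles$pixel_size)
  if (length(angpix) != 1) {
    stop("particles must share one pixel size", call. = FALSE)
  }
  zsign <- if (invert_defocus_z) 1 else -1
  sites <- orbit_sites(sym, v, merge_tol * angpix)
  mv <- vector_to_matrix(v)
  mp9 <- euler_to_matrix_many(particles$rot, particles$tilt, particles$psi)
  n <- nrow(particles)

  block_for <- function(s, k, rows) {
    site <- sites[[s]]
    a <- site$matrices[[k]] %*% mv
    sub9 <- mp9[rows, , drop = FALSE] %*% kronecker(a, diag(3))
    off <- mp9[rows, , drop = FALSE] %*%
      kronecker(matrix(site$position, ncol = 1), diag(3))
    eul <- matrix_to_euler_many(sub9)
    off_px <- off / angpix
    ctr_x <- image_size / 2 - particles$origin_x[rows] + off_px[, 1]
    ctr_y <- image_size / 2 - particles$origin_y[rows] + off_px[, 2]
    sx <- split_subpixel(ctr_x)
    sy <- split_subpixel(ctr_y)
    zpx <- off_px[, 3]
    img <- if ("image_name" %in% names(particles)) {
      particles$image_name[rows]
    } else NULL
    tibble::tibble(
      parent_id = particles$particle_id[rows],
      site_index = s - 1L,
      degen_index = k - 1L,
      n_degen = length(site$matrices),
      rot = eul$rot, tilt = eul$tilt, psi = eul$psi,
      coord_x = sx$int, coord_y = sy$int,
      origin_x = sx$origin, origin_y = sy$origin,
      center_x = ctr_x, center_y = ctr_y,
      z_height = zpx,
      elevation = asin(pmin(1, pmax(-1, off[, 3] / v$length))) * 180 / pi,
      defocus_u = particles$defocus_u[rows] + zsign * zpx * angpix,
      defocus_v = particles$defocus_v[rows] + zsign * zpx * angpix,
      astig_angle = particles$astig_angle[rows],
      voltage = particles$voltage[rows],
      cs = particles$cs[rows],
      amplitude_contrast = particles$amplitude_contrast[rows],
      pixel_size = angpix,
      !!!(if (is.null(img)) list() else list(image_name = img))
    )
  }

  blocks <- list()
  for (s in seq_along(sites)) {
    ndeg <- length(sites[[s]]$matrices)
    if (degenerate == "all") {
      for (k in seq_len(ndeg)) blocks[[length(blocks) + 1]] <- block_for(s, k, seq_len(n))
    } else if (degenerate == "first" || ndeg == 1) {
      blocks[[length(blocks) + 1]] <- block_for(s, 1L, seq_len(n))
    } else {
      ks <- if (is.null(seed)) {
        sample.int(ndeg, n, replace = TRUE)
      } else {
        withr::with_seed(seed + 1000L * s, sample.int(ndeg, n, replace = TRUE))
      }
      for (k in seq_len(ndeg)) {
        rows <- which(ks == k)
        if (length(rows)) blocks[[length(blocks) + 1]] <- block_for(s, k, rows)
      }
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(blocks), .data$parent_id,
                        .data$site_index, .data$degen_index)
  out$subparticle_id <- seq_len(nrow(out))
  out
}

#' Split a coordinate into an integer pixel and a sub-pixel origin
#'
#' Sub-particles are extracted on the integer pixel grid; the
#' non-integer remainder of the true position is kept as the origin so
#' no sub-pixel accuracy is lost. The integer part is the nearest pixel
#' (halves away from zero) and the origin is `integer - coordinate`, so
#' extracting at the integer position and shifting the image by the
#' origin re-centers it exactly; `|origin| <= 0.5` always.
#'
#' @param coord Numeric vector of coordinates in pixels.
#' @return A list with integer `int` and numeric `origin`.
#' @examples
#' split_subpixel(100.7) # extract at 101, origin +0.3
#' @export
split_subpixel <- function(coord) {
  stopifnot(all(is.finite(coord)))
  int <- sign(coord) * floor(abs(coord) + 0.5) # round half away from zero
  list(int = as.integer(int), origin = int - coord)
}

#' Shift CTF defocus for the sub-particle height along the beam
#'
#' A sub-particle displaced along the beam axis sits at a different
#' depth in the ice than the particle center, so its true defocus
#' differs by that height. Both defocus values are shifted by
#' `-z_height * pixel_size` (Angstrom): a sub-particle above the
#' particle center (positive z, towards the electron source) has its
#' underfocus reduced. The shift is linear in z, and the astigmatism
#' angle is unchanged. Set `invert_z = TRUE` to flip the convention.
#'
#' @param ctf A data frame (or one-row tibble) with `defocus_u`,
#'   `defocus_v` columns (Angstrom).
#' @param z_height Height in pixels, signed along the beam.
#' @param pixel_size Angstrom per pixel.
#' @param invert_z Flip the sign convention of z.
#' @return The CTF table with shifted defocus.
#' @export
adjust_defocus <- function(ctf, z_height, pixel_size, invert_z = FALSE) {
  stopifnot(pixel_size > 0)
  shift <- z_height * pixel_size * (if (invert_z) 1 else -1)
  ctf$defocus_u <- ctf$defocus_u + shift
  ctf$defocus_v <- ctf$defocus_v + shift
  ctf
}

#' Keep side views and drop top views of sub-particles
#'
#' Sub-particles seen from the side lie in the periphery of the
#' projected particle, where they overlap the bulk density least. A
#' record is a side view when its rotated subunit vector lies within
#' `side_max_angle` degrees of the image plane (elevation
#' `|90 - angle(vector, beam)| <= side_max_angle`); it is a top view
#' when the vector is within `top_angle` degrees of the beam axis
#' (either end).
#'
#' @param records Sub-particle records from [expand_subparticles()].
#' @param side_max_angle Maximum allowed elevation from the image plane
#'   in degrees, or `NULL` to keep all.
#' @param exclude_top_views Drop records whose vector is near the beam
#'   axis.
#' @param top_angle Angular radius of the top-view cone (degrees);
#'   defaults to `side_max_angle`.
#' @return The filtered records.
#' @export
filter_side_views <- function(records, side_max_angle = NULL,
                              exclude_top_views = FALSE,
                              top_angle = side_max_angle) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(side_max_angle)) {
    stopifnot(side_max_angle >= 0, side_max_angle <= 90)
    keep <- keep & abs(records$elevation) <= side_max_angle
  }
  if (isTRUE(exclude_top_views)) {
    if (is.null(top_angle)) stop("top_angle required to exclude top views", call. = FALSE)
    keep <- keep & abs(records$elevation) < 90 - top_angle
  }
  records[keep, , drop = FALSE]
}

#' Exclude sub-particles that overlap more than allowed
#'
#' Two sub-particle boxes from the same particle overlap along their
#' center line by `box_size - distance` pixels. When that exceeds
#' `max_overlap`, by default both members of the pair are removed (a
#' symmetric, order-independent rule); `remove = "one"` keeps the first
#' member of each offending pair instead. Records from different
#' particles are never compared.
#'
#' @param records Sub-particle records.
#' @param max_overlap Maximum allowed overlap in pixels.
#' @param box_size Sub-particle box size in pixels.
#' @param remove Remove `"both"` members of an overlapping pair or only
#'   the `"one"` encountered second.
#' @param reference Record set against which overlaps are evaluated
#'   (default: `records` itself). Passing the full, unfiltered
#'   expansion makes the overlap rule a pure predicate of the
#'   particle's geometry, so it commutes with other filters.
#' @return The filtered records.
#' @export
filter_overlaps <- function(records, max_overlap, box_size,
                            remove = c("both", "one"), reference = NULL) {
  remove <- match.arg(remove)
  if (is.null(reference)) reference <- records
  thr <- box_size - max_overlap
  if (thr <= 0) return(records)
  drop_ids <- unlist(lapply(split(reference, reference$parent_id), function(g) {
    k <- nrow(g)
    if (k < 2) return(integer())
    d <- as.matrix(stats::dist(cbind(g$center_x, g$center_y)))
    bad <- which(d < thr & upper.tri(d), arr.ind = TRUE)
    if (nrow(bad) == 0) return(integer())
    if (remove == "both") {
      g$subparticle_id[unique(c(bad[, 1], bad[, 2]))]
    } else {
      g$subparticle_id[unique(bad[, 2])]
    }
  }))
  records[!records$subparticle_id %in% drop_ids, , drop = FALSE]
}

#' Create sub-particles from a particle table in one call
#'
#' Convenience wrapper chaining [expand_subparticles()],
#' [filter_side_views()] and [filter_overlaps()].
#'
#' @inheritParams expand_subparticles
#' @inheritParams filter_side_views
#' @inheritParams filter_overlaps
#' @param box_size Sub-particle box size in pixels (needed only when
#'   `max_overlap` is given).
#' @return A tibble of sub-particle records.
#' @export
create_subparticles <- function(particles, sym, v, image_size,
                                merge_tol = 1, seed = NULL,
                                side_max_angle = NULL, exclude_top_views = FALSE,
                                max_overlap = NULL, box_size = NULL,
                                degenerate = "random", invert_defocus_z = FALSE) {
  records <- expand_subparticles(particles, sym, v, image_size,
                                 merge_tol = merge_tol,
                                 degenerate = degenerate, seed = seed,
                                 invert_defocus_z = invert_defocus_z)
  full <- records
  records <- filter_side_views(records, side_max_angle, exclude_top_views)
  if (!is.null(max_overlap)) {
    if (is.null(box_size)) stop("box_size required with max_overlap", call. = FALSE)
    records <- filter_overlaps(records, max_overlap, box_size, reference = full)
  }
  records
}

#' Extract sub-particle images from particle images
#'
#' Cuts the `box_size` window centered on each record's integer
#' extraction coordinate out of its parent particle image. Windows
#' extending past the image edge are skipped and counted. Optionally
#' each sub-image is normalized to zero mean and unit variance over a
#' background annulus (radius > 0.4 box).
#'
#' @param images An [image_stack()] (or 3D array) of particle images;
#'   slice `i` is the image of `particle_id == i`.
#' @param records Sub-particle records from [expand_subparticles()].
#' @param box_size Even box size in pixels.
#' @param normalize Normalize over the background annulus.
#' @return A list with `stack` (an [image_stack()] of the extracted
#'   boxes), `records` (the surviving records, in stack order) and
#'   `n_skipped`.
#' @export
extract_subparticles <- function(images, records, box_size, normalize = FALSE) {
  stopifnot(box_size %% 2 == 0)
  angpix <- if (inherits(images, "image_stack")) images$pixel_size else records$pixel_size[1]
  arr <- map_data(images)
  nsrc <- dim(arr)[1]
  half <- box_size / 2
  # 0-based window [coord-half, coord+half-1] must lie inside [0, nsrc-1]
  ok <- records$coord_x - half >= 0 & records$coord_x + half - 1 <= nsrc - 1 &
    records$coord_y - half >= 0 & records$coord_y + half - 1 <= nsrc - 1 &
    records$parent_id >= 1 & records$parent_id <= dim(arr)[3]
  kept <- records[ok, , drop = FALSE]
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    message(n_skipped, " sub-particle(s) extended past the image edge and were skipped")
  }
  out <- array(0, c(box_size, box_size, nrow(kept)))
  if (normalize) {
    r <- radius_grid(c(box_size, box_size))
    bg <- r > 0.4 * box_size
  }
  for (i in seq_len(nrow(kept))) {
    xs <- (kept$coord_x[i] - half):(kept$coord_x[i] + half - 1) + 1L
    ys <- (kept$coord_y[i] - half):(kept$coord_y[i] + half - 1) + 1L
    win <- arr[xs, ys, kept$parent_id[i]]
    if (normalize) {
      mu <- mean(win[bg]); sdev <- stats::sd(win[bg])
      win <- if (sdev > 0) (win - mu) / sdev else win - mu
    }
    out[, , i] <- win
  }
  list(stack = image_stack(out, angpix), records = kept, n_skipped = n_skipped)
}

#' Occupancy from sub-particle class counts
#'
#' After classifying sub-particles into classes labelled occupied or
#' empty, the site occupancy is the occupied fraction of all counted
#' sub-particles, truncated to an integer percentage, and the average
#' copy number per particle is that fraction of the sites on each
#' particle, rounded to the nearest integer. Classes to be disregarded
#' (e.g. junk classes) are simply omitted by the caller.
#'
#' @param class_counts Integer vector of sub-particles per class.
#' @param occupied_flags Logical vector: is each class occupied?
#' @param sites_per_particle Number of putative binding sites per
#'   particle.
#' @return A one-row tibble with `percent_occupied`,
#'   `copies_per_particle`, `n_occupied` and `n_total`.
#' @examples
#' occupancy_summary(c(14721, 13912, 14583, 28078),
#'                   c(TRUE, TRUE, TRUE, FALSE), 20)
#' @export
occupancy_summary <- function(class_counts, occupied_flags, sites_per_particle) {
  stopifnot(length(class_counts) == length(occupied_flags),
            all(class_counts >= 0))
  total <- sum(class_counts)
  if (total == 0) stop("occupancy undefined: all class counts are zero", call. = FALSE)
  occ <- sum(class_counts[occupied_flags])
  percent <- floor(100 * occ / total)
  tibble::tibble(
    percent_occupied = percent,
    copies_per_particle = round(percent / 100 * sites_per_particle),
    n_occupied = occ,
    n_total = total
  )
}
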