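#' Specification of a symmetric shell phantom with an asymmetric subunit
#'
#' The synthetic ground truth used throughout the package emulates a
#' symmetric protein shell carrying a sub-stoichiometric, asymmetric
#' subunit at a symmetry-axis site (the situation of a viral polymerase
#' bound under some of the threefold positions of an icosahedral
#' capsid). The shell is a union of Gaussian blobs at one symmetry
#' orbit of directions; the subunit is a two-blob cluster -- a main
#' blob on the site axis plus a smaller satellite off the axis -- so
#' that the n degenerate orientations around the site axis produce
#' distinguishable densities. Each site is occupied with probability
#' `occupancy`, and an occupied site carries one of the degenerate
#' orientations chosen uniformly at random.
#'
#' All lengths are in Angstrom.
#'
#' @param sym Symmetry label of the shell (default icosahedral).
#' @param site_axis Direction of the subunit site (default a threefold
#'   axis of the icosahedral I2 setting).
#' @param site_radius Radius of the subunit center.
#' @param shell_axis Direction whose orbit carries the shell blobs
#'   (default a fivefold axis).
#' @param shell_radius,shell_sigma,shell_amp Shell blob geometry.
#' @param subunit_sigma,subunit_amp Main subunit blob.
#' @param satellite_offset Satellite position in the subunit frame
#'   (z along the site axis); its off-axis component is what breaks the
#'   axial degeneracy.
#' @param satellite_sigma,satellite_amp Satellite blob.
#' @param occupancy Probability that a site is occupied.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(sym = "I",
                         site_axis = c(1, 1, 1),
                         site_radius = 100,
                         shell_axis = c(0, 1, (1 + sqrt(5)) / 2),
                         shell_radius = 130,
                         shell_sigma = 12,
                         shell_amp = 1,
                         subunit_sigma = 10,
                         subunit_amp = 1.5,
                         satellite_offset = c(15, 0, 0),
                         satellite_sigma = 6,
                         satellite_amp = 1.2,
                         occupancy = 0.6) {
  stopifnot(occupancy >= 0, occupancy <= 1, site_radius > 0, shell_radius > 0)
  structure(list(sym = sym, site_axis = site_axis, site_radius = site_radius,
                 shell_axis = shell_axis, shell_radius = shell_radius,
                 shell_sigma = shell_sigma, shell_amp = shell_amp,
                 subunit_sigma = subunit_sigma, subunit_amp = subunit_amp,
                 satellite_offset = satellite_offset,
                 satellite_sigma = satellite_sigma,
                 satellite_amp = satellite_amp,
                 occupancy = occupancy),
            class = "phantom_spec")
}

phantom_group <- function(spec) point_group(spec$sym)

phantom_vector <- function(spec) subunit_vector(spec$site_axis, spec$site_radius)

phantom_sites <- function(spec) {
  orbit_sites(phantom_group(spec), phantom_vector(spec),
              merge_tol = 1e-3 * spec$site_radius)
}

# Precomputed geometry shared across many particles of one spec.
phantom_geometry <- function(spec) {
  group <- phantom_group(spec)
  sites <- phantom_sites(spec)
  shell_sites <- orbit_sites(group,
                             subunit_vector(spec$shell_axis, spec$shell_radius),
                             merge_tol = 1e-3 * spec$shell_radius)
  shell_pos <- do.call(rbind, lapply(shell_sites, function(s) s$position))
  list(group = group, sites = sites, shell_pos = shell_pos,
       mv = vector_to_matrix(phantom_vector(spec)))
}

# Draw per-site occupancy and degenerate-orientation indices.
draw_site_states <- function(spec, n_sites, n_degen) {
  tibble::tibble(
    site_index = seq_len(n_sites) - 1L,
    occupied = stats::runif(n_sites) < spec$occupancy,
    degen_index = sample.int(n_degen, n_sites, replace = TRUE) - 1L
  )
}

# Blob table (x, y, z in A relative to the map center; sigma, amp) for
# one particle in a given occupancy state.
phantom_blobs <- function(spec, site_states, include_shell = TRUE,
                          include_subunit = TRUE, geom = NULL) {
  if (is.null(geom)) geom <- phantom_geometry(spec)
  blobs <- list()
  if (include_shell) {
    pos <- geom$shell_pos
    blobs[[1]] <- tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                                 sigma = spec$shell_sigma, amp = spec$shell_amp)
  }
  if (include_subunit) {
    sites <- geom$sites
    mv <- geom$mv
    occ <- site_states[site_states$occupied, , drop = FALSE]
    if (nrow(occ) > 0) {
      sub <- lapply(seq_len(nrow(occ)), function(i) {
        s <- sites[[occ$site_index[i] + 1L]]
        m_site <- s$matrices[[occ$degen_index[i] + 1L]] %*% mv
        sat <- as.numeric(m_site %*% spec$satellite_offset) + s$position
        tibble::tibble(
          x = c(s$position[1], sat[1]),
          y = c(s$position[2], sat[2]),
          z = c(s$position[3], sat[3]),
          sigma = c(spec$subunit_sigma, spec$satellite_sigma),
          amp = c(spec$subunit_amp, spec$satellite_amp)
        )
      })
      blobs[[length(blobs) + 1]] <- dplyr::bind_rows(sub)
    }
  }
  dplyr::bind_rows(blobs)
}

# Render a blob table as a 3D voxel array (n^3, pixel_size A/px),
# evaluating each Gaussian over a +-4 sigma local support.
render_blob_map <- function(blobs, n, pixel_size) {
  arr <- array(0, c(n, n, n))
  c0 <- n / 2 # 0-based center
  for (i in seq_len(nrow(blobs))) {
    s_px <- blobs$sigma[i] / pixel_size
    ctr <- c(blobs$x[i], blobs$y[i], blobs$z[i]) / pixel_size + c0
    lo <- pmax(0, floor(ctr - 4 * s_px))
    hi <- pmin(n - 1, ceiling(ctr + 4 * s_px))
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    gx <- exp(-(ix - ctr[1])^2 / (2 * s_px^2))
    gy <- exp(-(iy - ctr[2])^2 / (2 * s_px^2))
    gz <- exp(-(iz - ctr[3])^2 / (2 * s_px^2))
    arr[ix + 1, iy + 1, iz + 1] <- arr[ix + 1, iy + 1, iz + 1] +
      blobs$amp[i] * outer(outer(gx, gy), gz)
  }
  arr
}

# Analytic projection of a blob table: the line integral of an
# isotropic Gaussian is a 2D Gaussian of the same sigma with integrated
# amplitude amp * sigma_px * sqrt(2*pi) (in voxel-sum units, matching
# the Fourier projector's scale). `pose` is the rotation matrix;
# `origin` the alignment origin in px (the rendered particle is
# displaced by -origin).
render_projection <- function(blobs, pose, origin, n, pixel_size) {
  img <- matrix(0, n, n)
  c0 <- n / 2
  for (i in seq_len(nrow(blobs))) {
    p <- pose %*% c(blobs$x[i], blobs$y[i], blobs$z[i])
    u <- p[1:2] / pixel_size - origin + c0
    s_px <- blobs$sigma[i] / pixel_size
    a2 <- blobs$amp[i] * s_px * sqrt(2 * pi)
    lo <- pmax(0, floor(u - 4 * s_px))
    hi <- pmin(n - 1, ceiling(u + 4 * s_px))
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]
    gx <- exp(-(ix - u[1])^2 / (2 * s_px^2))
    gy <- exp(-(iy - u[2])^2 / (2 * s_px^2))
    img[ix + 1, iy + 1] <- img[ix + 1, iy + 1] + a2 * outer(gx, gy)
  }
  img
}

#' Build the ground-truth phantom maps for one occupancy state
#'
#' Renders the full phantom (shell plus occupied subunits), the shell
#' alone, and the subunits alone as voxel maps, together with the
#' manifest of per-site states, drawn with the given seed.
#'
#' @param spec A [phantom_spec()].
#' @param n Grid side length in pixels (even).
#' @param pixel_size Angstrom per pixel.
#' @param seed Seed for the occupancy and orientation draw.
#' @param site_states Optional explicit manifest (overrides the draw).
#' @return A list with `full`, `shell_only`, `subunit_only`
#'   ([density_map()]s) and `sites` (manifest tibble).
#' @export
make_phantom <- function(spec, n, pixel_size, seed = 1, site_states = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), n %% 2 == 0)
  extent <- max(spec$shell_radius + 4 * spec$shell_sigma,
                spec$site_radius + sqrt(sum(spec$satellite_offset^2)) +
                  4 * spec$subunit_sigma)
  if (extent > n / 2 * pixel_size) {
    stop("phantom blobs exceed the grid (need ", round(2 * extent), " A field)",
         call. = FALSE)
  }
  geom <- phantom_geometry(spec)
  sites <- geom$sites
  if (is.null(site_states)) {
    site_states <- withr::with_seed(seed, {
      draw_site_states(spec, length(sites), length(sites[[1]]$matrices))
    })
  }
  shell <- render_blob_map(phantom_blobs(spec, site_states, TRUE, FALSE, geom),
                           n, pixel_size)
  subunit <- render_blob_map(phantom_blobs(spec, site_states, FALSE, TRUE, geom),
                             n, pixel_size)
  list(full = density_map(shell + subunit, pixel_size),
       shell_only = density_map(shell, pixel_size),
       subunit_only = density_map(subunit, pixel_size),
       sites = site_states)
}

#' The subunit reference density in its own frame
#'
#' Renders the asymmetric subunit cluster centered on a box, in the
#' reference orientation (site axis along z). This is the ground truth
#' a localized reconstruction of correctly oriented sub-particles
#' should recover.
#'
#' @param spec A [phantom_spec()].
#' @param box Box side length in pixels.
#' @param pixel_size Angstrom per pixel.
#' @return A [density_map()].
#' @export
render_subunit_reference <- function(spec, box, pixel_size) {
  blobs <- tibble::tibble(
    x = c(0, spec$satellite_offset[1]),
    y = c(0, spec$satellite_offset[2]),
    z = c(0, spec$satellite_offset[3]),
    sigma = c(spec$subunit_sigma, spec$satellite_sigma),
    amp = c(spec$subunit_amp, spec$satellite_amp)
  )
  density_map(render_blob_map(blobs, box, pixel_size), pixel_size)
}

#' Simulate a CTF-modulated, noisy particle data set from a phantom
#'
#' For each particle: draws a uniform orientation over SO(3) (or takes
#' a supplied pose), a sub-pixel alignment origin, a defocus, and a
#' per-site occupancy state; renders the projection of that particle's
#' own phantom analytically (exact Gaussian line integrals); applies
#' the full CTF; and adds white Gaussian noise scaled to the requested
#' signal-to-noise ratio (`var(signal)/var(noise)` per image).
#' Optionally a smooth random background field emulating unsubtractable
#' structural noise (e.g. internal genome density) is added before the
#' CTF.
#'
#' @param spec A [phantom_spec()].
#' @param n_particles Number of particle images.
#' @param n Image side length in pixels.
#' @param pixel_size Angstrom per pixel.
#' @param snr Signal-to-noise ratio of the additive noise (`Inf` for
#'   noise-free).
#' @param defocus_range Range (Angstrom) for the uniform defocus draw.
#' @param voltage,cs,amplitude_contrast Microscope parameters (kV, mm,
#'   fraction).
#' @param origin_range Alignment origins are drawn uniformly in
#'   `[-origin_range, origin_range]` pixels.
#' @param structural_noise_sd Standard deviation of the optional
#'   low-frequency background field (0 to disable), relative to the
#'   clean signal standard deviation.
#' @param poses Optional tibble of poses (`rot`, `tilt`, `psi`) to use
#'   instead of random ones.
#' @param seed Integer seed; the simulation is bit-reproducible.
#' @return A list with `images` (an [image_stack()]), `particles` (the
#'   STAR-ready particle tibble with true poses and CTF), `manifest`
#'   (per particle x site: `occupied`, `degen_index`) and `spec`.
#' @export
simulate_particles <- function(spec, n_particles, n = 80, pixel_size = 4.5,
                               snr = 0.1, defocus_range = c(10000, 30000),
                               voltage = 300, cs = 2, amplitude_contrast = 0.07,
                               origin_range = 2, structural_noise_sd = 0,
                               poses = NULL, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"), n_particles >= 1, n %% 2 == 0)
  geom <- phantom_geometry(spec)
  n_sites <- length(geom$sites)
  n_degen <- length(geom$sites[[1]]$matrices)
  withr::with_seed(seed, {
    particles <- tibble::tibble(
      particle_id = seq_len(n_particles),
      rot = if (is.null(poses)) stats::runif(n_particles, -180, 180) else poses$rot,
      tilt = if (is.null(poses)) {
        acos(stats::runif(n_particles, -1, 1)) * 180 / pi
      } else poses$tilt,
      psi = if (is.null(poses)) stats::runif(n_particles, -180, 180) else poses$psi,
      origin_x = stats::runif(n_particles, -origin_range, origin_range),
      origin_y = stats::runif(n_particles, -origin_range, origin_range),
      defocus_u = stats::runif(n_particles, defocus_range[1], defocus_range[2]),
      defocus_v = NA_real_,
      astig_angle = stats::runif(n_particles, 0, 180),
      voltage = voltage,
      cs = cs,
      amplitude_contrast = amplitude_contrast,
      pixel_size = pixel_size
    )
    particles$defocus_v <- particles$defocus_u - stats::runif(n_particles, 0, 400)
    particles$image_name <- sprintf("%06d@particles.mrcs", particles$particle_id)
    manifest <- dplyr::bind_rows(lapply(seq_len(n_particles), function(i) {
      st <- draw_site_states(spec, n_sites, n_degen)
      st$particle_id <- i
      st
    }))
    stack <- array(0, c(n, n, n_particles))
    for (i in seq_len(n_particles)) {
      st <- manifest[manifest$particle_id == i, ]
      blobs <- phantom_blobs(spec, st, geom = geom)
      pose <- euler_to_matrix(particles$rot[i], particles$tilt[i], particles$psi[i])
      img <- render_projection(blobs, pose,
                               c(particles$origin_x[i], particles$origin_y[i]),
                               n, pixel_size)
      if (structural_noise_sd > 0) {
        field <- matrix(stats::rnorm(n * n), n, n)
        field <- lowpass_filter(field, 8 * pixel_size, pixel_size)
        img <- img + structural_noise_sd * stats::sd(img) * field / stats::sd(field)
      }
      img <- apply_ctf(img, particles[i, ], pixel_size, "full")
      if (is.finite(snr)) {
        # snr is defined against the clean image as recorded (post-CTF)
        img <- img + stats::rnorm(n * n, sd = stats::sd(img) / sqrt(snr))
      }
      stack[, , i] <- img
    }
    list(images = image_stack(stack, pixel_size), particles = particles,
         manifest = manifest[c("particle_id", "site_index", "occupied",
                               "degen_index")],
         spec = spec)
  })
}

#' Score sub-particles for subunit occupancy
#'
#' A per-record matched-filter detector followed by a constrained
#' mixture fit, standing in for the 3D classification a full workflow
#' would run. Each (ideally bulk-subtracted) sub-particle is correlated
#' with the expected subunit reprojection within its footprint: a
#' mean-centered Gaussian template of width `template_sigma` at the
#' sub-particle center (box center shifted by minus the record's
#' origin), modulated by the record's own CTF. The matched-filter score
#' is divided by the image noise level measured outside the footprint,
#' giving a z-score whose distribution over empty sites is known to be
#' close to standard normal. Occupancy is then estimated by
#' expectation-maximization of a two-component mixture in which the
#' empty component is pinned at zero mean -- this anchoring keeps the
#' occupancy estimate well identified even when the two score
#' populations overlap substantially. Records are labelled occupied
#' where the posterior exceeds 1/2.
#'
#' @param substack An [image_stack()] of extracted, bulk-subtracted
#'   sub-particles.
#' @param records The matching sub-particle records.
#' @param template_sigma Width (Angstrom) of the Gaussian subunit
#'   template, typically the subunit blob sigma.
#' @return The records with `score` (z-score), `score_raw` (the
#'   matched-filter amplitude before noise normalization, useful on
#'   noise-free data) and `occupied_pred` columns, plus attributes
#'   `occupancy` (estimated occupied fraction), `mixture` (fitted
#'   parameters) and `threshold` (z at posterior 1/2).
#' @export
score_occupancy <- function(substack, records, template_sigma) {
  stopifnot(inherits(substack, "image_stack"))
  arr <- substack$data
  b <- dim(arr)[1]
  angpix <- substack$pixel_size
  s_px <- template_sigma / angpix
  ax <- seq_len(b) - 1 - b / 2
  raw <- numeric(nrow(records))
  z <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    img <- arr[, , i]
    gx <- exp(-(ax + records$origin_x[i])^2 / (2 * s_px^2))
    gy <- exp(-(ax + records$origin_y[i])^2 / (2 * s_px^2))
    tmpl <- outer(gx, gy)
    tmpl <- tmpl - mean(tmpl)
    tmpl <- apply_ctf(tmpl, records[i, ], angpix, "full")
    fp <- outer((ax + records$origin_x[i])^2,
                (ax + records$origin_y[i])^2, "+") <= (3 * s_px)^2
    noise_sd <- max(stats::mad(img[!fp]), 1e-12)
    raw[i] <- sum(img * tmpl) / sqrt(sum(tmpl^2))
    z[i] <- raw[i] / noise_sd
  }
  fit <- null_anchored_mixture(z)
  post <- fit$posterior
  out <- records
  out$score <- z
  out$score_raw <- raw
  out$occupied_prob <- post
  out$occupied_pred <- post > 0.5
  attr(out, "occupancy") <- fit$weight
  attr(out, "mixture") <- fit[c("weight", "mu1", "s1", "s0")]
  attr(out, "threshold") <- fit$threshold
  out
}

# Two-component Gaussian mixture with the null component pinned at
# mean zero: z ~ (1-w) N(0, s0) + w N(mu1, s1). When the fitted signal
# component is not separated from the null (mu1 below half a null sd),
# the mixture is unidentifiable and the occupied fraction falls back to
# the z > 3 outlier rate.
null_anchored_mixture <- function(z, max_iter = 200, tol = 1e-8) {
  w <- 0.5
  mu1 <- as.numeric(stats::quantile(z, 0.8))
  s1 <- 1; s0 <- 1
  g <- rep(0.5, length(z))
  ok <- TRUE
  for (it in seq_len(max_iter)) {
    d1 <- w * stats::dnorm(z, mu1, s1)
    d0 <- (1 - w) * stats::dnorm(z, 0, s0)
    g_new <- d1 / (d1 + d0)
    g_new[!is.finite(g_new)] <- 0.5
    w_new <- mean(g_new)
    mu1 <- sum(g_new * z) / max(sum(g_new), 1e-12)
    s1 <- sqrt(sum(g_new * (z - mu1)^2) / max(sum(g_new), 1e-12))
    s0 <- sqrt(sum((1 - g_new) * z^2) / max(sum(1 - g_new), 1e-12))
    if (!all(is.finite(c(w_new, mu1, s1, s0)))) { ok <- FALSE; break }
    s1 <- max(s1, 1e-6); s0 <- max(s0, 1e-6)
    done <- abs(w_new - w) < tol
    w <- w_new; g <- g_new
    if (done && it > 5) break
  }
  if (!ok || !is.finite(mu1) || mu1 < 0.5 * s0) {
    w <- mean(z > 3)
    g <- as.numeric(z > 3)
  }
  thr <- if (any(g > 0.5) && any(g <= 0.5)) {
    (max(z[g <= 0.5]) + min(z[g > 0.5])) / 2
  } else if (all(g > 0.5)) min(z) else max(z)
  list(weight = w, mu1 = mu1, s1 = s1, s0 = s0, posterior = g,
       threshold = thr)
}
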