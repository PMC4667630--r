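# Shared fixtures and independent oracles for the test suite.

rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

# Particle table with uniform random orientations and typical CTF values.
random_particles <- function(n, pixel_size, seed) {
  withr::with_seed(seed, tibble::tibble(
    particle_id = seq_len(n),
    rot = stats::runif(n, -180, 180),
    tilt = acos(stats::runif(n, -1, 1)) * 180 / pi,
    psi = stats::runif(n, -180, 180),
    origin_x = stats::runif(n, -2, 2),
    origin_y = stats::runif(n, -2, 2),
    defocus_u = stats::runif(n, 10000, 30000),
    defocus_v = stats::runif(n, 10000, 30000),
    astig_angle = stats::runif(n, 0, 180),
    voltage = 300,
    cs = 2,
    amplitude_contrast = 0.07,
    pixel_size = pixel_size
  ))
}

# Independent elemental rotations (column-vector convention) for the
# Euler-composition oracle.
oracle_rz <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
oracle_ry <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# Blob-model fixtures: a compact band-limited test object and its exact
# analytic projection (Gaussian line integrals), independent of the
# package's Fourier projector.
fixture_blobs <- function() {
  tibble::tibble(
    x = c(0, 18, -10), y = c(8, -5, -12), z = c(-4, 10, 6),
    sigma = c(16, 12, 14), amp = c(1, 0.8, 0.9)
  )
}

analytic_projection <- function(blobs, pose, origin, n, pixel_size) {
  img <- matrix(0, n, n)
  c0 <- n / 2
  ax <- seq_len(n) - 1
  for (i in seq_len(nrow(blobs))) {
    p <- pose %*% c(blobs$x[i], blobs$y[i], blobs$z[i])
    u <- p[1:2] / pixel_size - origin + c0
    s_px <- blobs$sigma[i] / pixel_size
    a2 <- blobs$amp[i] * s_px * sqrt(2 * pi)
    gx <- exp(-(ax - u[1])^2 / (2 * s_px^2))
    gy <- exp(-(ax - u[2])^2 / (2 * s_px^2))
    img <- img + a2 * outer(gx, gy)
  }
  img
}

blob_voxel_map <- function(blobs, n, pixel_size) {
  arr <- array(0, c(n, n, n))
  ax <- seq_len(n) - 1 - n / 2
  for (i in seq_len(nrow(blobs))) {
    s_px <- blobs$sigma[i] / pixel_size
    gx <- exp(-(ax - blobs$x[i] / pixel_size)^2 / (2 * s_px^2))
    gy <- exp(-(ax - blobs$y[i] / pixel_size)^2 / (2 * s_px^2))
    gz <- exp(-(ax - blobs$z[i] / pixel_size)^2 / (2 * s_px^2))
    arr <- arr + blobs$amp[i] * outer(outer(gx, gy), gz)
  }
  localrec::density_map(arr, pixel_size)
}

# Real-space rotate-and-sum projection oracle: Fourier-upsample the
# volume (exact for band-limited data), rotate by trilinear resampling
# on the fine grid, sum along the beam, and downsample the projection.
rotate_sum_projection <- function(map, euler, upsample = 4) {
  n <- dim(map$data)[1]
  nf <- upsample * n
  f <- localrec:::fft3_centered(map$data)
  up <- Re(localrec:::ifft3_centered(localrec:::pad_centered(f, nf))) * upsample^3
  m <- localrec::euler_to_matrix(euler[1], euler[2], euler[3])
  rot <- localrec:::.cpp_resample_rotated(up, dim(up), m)
  img <- apply(rot, c(1, 2), sum) / upsample
  fi <- localrec:::fft2_centered(img)
  Re(localrec:::ifft2_centered(localrec:::crop_centered(fi, n))) / upsample^2
}

# Center of mass of a (non-negative) image in 0-based pixel units.
center_of_mass <- function(img) {
  img <- img - min(img)
  ax <- seq_len(dim(img)[1]) - 1
  tot <- sum(img)
  c(sum(rowSums(img) * ax), sum(colSums(img) * ax)) / tot
}

# Small scaled-down phantom for fast pipeline tests.
test_phantom_spec <- function(...) {
  localrec::phantom_spec(...)
}
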