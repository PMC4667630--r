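std_ctf <- function(du = 15000, dv = 15000, astig = 0) {
  tibble::tibble(defocus_u = du, defocus_v = dv, astig_angle = astig,
                 voltage = 300, cs = 2, amplitude_contrast = 0.07)
}

test_that("spherical masks are placed, sized and bounded correctly", {
  n <- 64
  m <- make_spherical_mask(c(0, 0, 0), diameter = 20, n = n, pixel_size = 2)
  expect_true(all(m$data %in% c(0, 1))) # binary at edge width 0
  r_px <- 5
  expect_equal(sum(m$data), 4 / 3 * pi * r_px^3, tolerance = 0.1)

  soft <- make_spherical_mask(c(0, 0, 0), 20, n, 2, soft_edge = 3)
  expect_true(all(soft$data >= 0 & soft$data <= 1))
  expect_gt(sum(soft$data), sum(m$data))

  # off-center sphere at the mask center distance of the phi6 setup:
  # radius 100 A at 1.35 A/px = 74.07 px from the map center
  n2 <- 224
  v <- subunit_vector(c(1, 1, 1), 100)
  m2 <- make_spherical_mask(v, 80, n2, 1.35)
  idx <- which(m2$data == 1, arr.ind = TRUE) - 1 - n2 / 2
  ctr <- colMeans(idx)
  expect_equal(sqrt(sum(ctr^2)), 100 / 1.35, tolerance = 0.01)
  expect_error(make_spherical_mask(v, 400, 64, 1.35), "outside the grid")
})

test_that("mask symmetrization reproduces the symmetry orbit", {
  v <- subunit_vector(c(1, 1, 1), 100)
  m <- make_spherical_mask(v, 60, 64, 4.5)
  expect_equal(symmetrize_mask(m, "C1")$data, m$data)

  sym <- symmetrize_mask(m, "I")
  # 20 spheres on the threefold orbit, covering <= 20x one sphere
  expect_lte(sum(sym$data), 20 * sum(m$data) + 1e-6)
  expect_gt(sum(sym$data), 15 * sum(m$data)) # near-disjoint spheres
  sites <- localrec:::orbit_sites(point_group("I"), v, 1)
  for (s in sites) {
    px <- round(s$position / 4.5 + 32)
    expect_gt(sym$data[px[1] + 1, px[2] + 1, px[3] + 1], 0.9)
  }
  # idempotent up to trilinear blur confined to the mask edge shell
  twice <- symmetrize_mask(sym, "I")
  expect_lt(mean(abs(twice$data - sym$data)), 0.01)
  expect_gt(mean((twice$data > 0.5) == (sym$data > 0.5)), 0.995)
})

test_that("mask_to_background flattens only the masked region", {
  spec <- test_phantom_spec()
  ph <- make_phantom(spec, 80, 4.5, seed = 3)
  empty <- density_map(array(0, dim(ph$full$data)), 4.5)
  expect_equal(mask_to_background(ph$full, empty)$data, ph$full$data)

  # all but one voxel masked: everything else goes to background
  allbut <- array(1, c(16, 16, 16))
  allbut[1, 1, 1] <- 0
  mp <- density_map(array(stats::rnorm(16^3), c(16, 16, 16)), 2)
  res <- mask_to_background(mp, density_map(allbut, 2))
  expect_equal(stats::sd(res$data[-1]), 0, tolerance = 1e-12)
  expect_equal(res$data[1, 1, 1], mp$data[1, 1, 1])
  expect_error(
    mask_to_background(mp, density_map(array(1, c(16, 16, 16)), 2)),
    "covers the entire map")

  # phantom: removing the subunits leaves the shell
  v <- subunit_vector(c(1, 1, 1), 100)
  smask <- symmetrize_mask(make_spherical_mask(v, 80, 80, 4.5), "I")
  masked <- mask_to_background(ph$full, smask)
  expect_gt(cor(as.vector(masked$data), as.vector(ph$shell_only$data)), 0.99)
})

test_that("the Fourier-slice projector matches direct summation and is linear", {
  angpix <- 4.5
  n <- 48
  blobs <- fixture_blobs()
  map <- blob_voxel_map(blobs, n, angpix)

  # identity pose equals the sum along the beam axis
  p0 <- project_map(map, c(0, 0, 0))
  direct <- apply(map$data, c(1, 2), sum)
  expect_lt(rel_rms(p0, direct), 1e-3)

  # uniform map projects to a uniform image (value x depth) away from edges
  u <- density_map(array(2, c(32, 32, 32)), 1)
  pu <- project_map(u, c(0, 0, 0))
  # (a sharp-edged cube is not band-limited, so allow Gibbs ripple)
  inner <- pu[9:24, 9:24]
  expect_equal(mean(inner), 2 * 32, tolerance = 5e-3)
  expect_lt(stats::sd(inner) / mean(inner), 1e-2)

  # linearity
  m1 <- blob_voxel_map(blobs[1, ], n, angpix)
  m2 <- blob_voxel_map(blobs[2, ], n, angpix)
  e <- c(40, 70, -10)
  lhs <- project_map(density_map(2 * m1$data + 3 * m2$data, angpix), e)
  rhs <- 2 * project_map(m1, e) + 3 * project_map(m2, e)
  expect_lt(rel_rms(lhs, rhs), 1e-9)
})

test_that("Fourier-slice projections agree with rotate-and-sum over 100 poses", {
  angpix <- 4.5
  n <- 48
  map <- blob_voxel_map(fixture_blobs(), n, angpix)
  pj <- fourier_projector(map, pad = 4)
  withr::with_seed(15, {
    worst <- 0
    for (i in 1:100) {
      e <- c(runif(1, -180, 180), acos(runif(1, -1, 1)) * 180 / pi,
             runif(1, -180, 180))
      pf <- project_slice(pj, e)
      pr <- rotate_sum_projection(map, e)
      worst <- max(worst, rel_rms(pf, pr))
    }
  })
  expect_lt(worst, 1e-3)
})

test_that("CTF evaluation matches its closed form and zero structure", {
  ctf <- std_ctf()
  expect_equal(ctf_evaluate(ctf, 0, 0), -0.07)

  # independent oracle: lambda and chi written out from first principles,
  # first zero where chi = pi - asin(A)
  v <- 300 * 1e3
  lambda <- 12.2643 / sqrt(v * (1 + v * 0.978466e-6))
  chi <- function(s) pi * lambda * 15000 * s^2 - pi / 2 * 2e7 * lambda^3 * s^4
  s_zero_oracle <- stats::uniroot(function(s) chi(s) - (pi - asin(0.07)),
                                  c(0.001, 0.08), tol = 1e-12)$root
  s_zero_pkg <- stats::uniroot(function(s) ctf_evaluate(ctf, s, 0),
                               c(0.001, 0.08), tol = 1e-12)$root
  expect_lt(abs(s_zero_pkg - s_zero_oracle), 1e-4)

  # astigmatism: defocus varies with azimuth
  actf <- std_ctf(16000, 14000, 45)
  expect_equal(ctf_evaluate(actf, 0.01, 45), ctf_evaluate(std_ctf(16000, 16000), 0.01, 0))
  expect_equal(ctf_evaluate(actf, 0.01, 135), ctf_evaluate(std_ctf(14000, 14000), 0.01, 0))
})

test_that("phase flipping preserves Fourier amplitudes exactly", {
  withr::with_seed(16, img <- matrix(rnorm(64 * 64), 64, 64))
  flipped <- apply_ctf(img, std_ctf(), 1.35, "phase_flip")
  a1 <- Mod(localrec:::fft2_centered(img))
  a2 <- Mod(localrec:::fft2_centered(flipped))
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("subtracting the masked bulk leaves the subunit projection", {
  spec <- test_phantom_spec()
  ph <- make_phantom(spec, 80, 4.5, seed = 3)
  v <- subunit_vector(c(1, 1, 1), 100)
  smask <- symmetrize_mask(make_spherical_mask(v, 80, 80, 4.5), "I")
  masked <- mask_to_background(ph$full, smask)
  rec <- cbind(tibble::tibble(particle_id = 1, rot = 33, tilt = 61, psi = -50,
                              origin_x = 1.2, origin_y = -0.7, pixel_size = 4.5),
               std_ctf(18000, 17800, 30))
  img <- apply_ctf(project_map(ph$full, c(33, 61, -50), c(1.2, -0.7)), rec,
                   4.5, "full")
  res <- subtract_projection(img, masked, rec)
  want <- apply_ctf(project_map(ph$subunit_only, c(33, 61, -50), c(1.2, -0.7)),
                    rec, 4.5, "full")
  expect_lt(rel_rms(res, want), 0.05)

  # all-zero masked map leaves the image unchanged
  zero <- density_map(array(0, c(80, 80, 80)), 4.5)
  expect_equal(subtract_projection(img, zero, rec), img, tolerance = 1e-12)

  # subtraction is linear: removing A+B equals removing A then B
  mA <- ph$shell_only
  mB <- ph$subunit_only
  both <- density_map(mA$data + mB$data, 4.5)
  lhs <- subtract_projection(img, both, rec, scale = FALSE)
  rhs <- subtract_projection(subtract_projection(img, mA, rec, scale = FALSE),
                             mB, rec, scale = FALSE)
  expect_lt(max(abs(lhs - rhs)), 1e-6 * max(abs(img)))

  expect_error(subtract_projection(img, density_map(array(0, c(80, 80, 80)), 2),
                                   rec), "pixel size mismatch")
})
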