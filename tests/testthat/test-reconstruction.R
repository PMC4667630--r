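make_projection_set <- function(map, k, seed, noise_sd = 0) {
  n <- dim(map$data)[1]
  pj <- fourier_projector(map)
  withr::with_seed(seed, {
    rec <- tibble::tibble(
      rot = runif(k, -180, 180), tilt = acos(runif(k, -1, 1)) * 180 / pi,
      psi = runif(k, -180, 180),
      origin_x = runif(k, -2, 2), origin_y = runif(k, -2, 2),
      pixel_size = map$pixel_size
    )
    imgs <- array(0, c(n, n, k))
    for (i in seq_len(k)) {
      imgs[, , i] <- project_slice(pj, c(rec$rot[i], rec$tilt[i], rec$psi[i]),
                                   c(rec$origin_x[i], rec$origin_y[i]))
      if (noise_sd > 0) imgs[, , i] <- imgs[, , i] + rnorm(n * n, sd = noise_sd)
    }
    list(images = image_stack(imgs, map$pixel_size), records = rec)
  })
}

test_that("direct Fourier inversion recovers the phantom from projections", {
  angpix <- 4.5
  map <- blob_voxel_map(fixture_blobs(), 48, angpix)
  ps <- make_projection_set(map, 300, seed = 17)
  rec <- reconstruct_map(ps$images, ps$records, ctf_mode = "none")
  lp_true <- lowpass_filter(map, 3 * angpix)
  lp_rec <- lowpass_filter(rec, 3 * angpix)
  expect_gt(cor(as.vector(lp_true$data), as.vector(lp_rec$data)), 0.95)
  expect_equal(max(lp_rec$data) / max(lp_true$data), 1, tolerance = 0.1)

  # duplicating every image leaves the reconstruction unchanged
  arr <- ps$images$data
  dup <- reconstruct_map(image_stack(arr[, , c(1:300, 1:300)], angpix),
                         ps$records[c(1:300, 1:300), ], ctf_mode = "none")
  expect_lt(max(abs(dup$data - rec$data)), 1e-9 * max(abs(rec$data)))

  expect_error(reconstruct_map(image_stack(array(0, c(16, 16, 0)), 1),
                               tibble::tibble()), "empty")
})

test_that("a single identity-pose slice backprojects consistently", {
  angpix <- 4.5
  map <- blob_voxel_map(fixture_blobs(), 48, angpix)
  img <- project_map(map, c(0, 0, 0))
  one <- reconstruct_map(image_stack(array(img, c(48, 48, 1)), angpix),
                         tibble::tibble(rot = 0, tilt = 0, psi = 0,
                                        origin_x = 0, origin_y = 0,
                                        pixel_size = angpix),
                         ctf_mode = "none")
  beam_sum <- apply(one$data, c(1, 2), sum)
  expect_gt(cor(as.vector(beam_sum), as.vector(img)), 0.999)
  expect_equal(sum(beam_sum * img) / sum(img^2), 1, tolerance = 0.5)
})

test_that("reconstruction with full CTF correction restores the phantom", {
  angpix <- 4.5
  n <- 48
  map <- blob_voxel_map(fixture_blobs(), n, angpix)
  k <- 200
  ps <- make_projection_set(map, k, seed = 18)
  withr::with_seed(19, {
    ctf_cols <- tibble::tibble(
      defocus_u = runif(k, 10000, 30000),
      defocus_v = runif(k, 10000, 30000),
      astig_angle = runif(k, 0, 180), voltage = 300, cs = 2,
      amplitude_contrast = 0.07
    )
  })
  rec_tab <- dplyr::bind_cols(ps$records, ctf_cols)
  arr <- ps$images$data
  for (i in seq_len(k)) {
    arr[, , i] <- apply_ctf(arr[, , i], rec_tab[i, ], angpix, "full")
  }
  out <- reconstruct_map(image_stack(arr, angpix), rec_tab, ctf_mode = "full")
  lp_true <- lowpass_filter(map, 3 * angpix)
  lp_rec <- lowpass_filter(out, 3 * angpix)
  expect_gt(cor(as.vector(lp_true$data), as.vector(lp_rec$data)), 0.95)
})

test_that("FSC honours its self, negation and noise bounds", {
  angpix <- 4.5
  map <- blob_voxel_map(fixture_blobs(), 48, angpix)
  f <- fsc_curve(map, map)
  expect_true(all(abs(f$fsc - 1) < 1e-10))
  expect_true(all(diff(f$shell) > 0))
  neg <- density_map(-map$data, angpix)
  expect_true(all(abs(fsc_curve(map, neg)$fsc + 1) < 1e-10))

  withr::with_seed(20, {
    n1 <- density_map(array(rnorm(48^3), c(48, 48, 48)), angpix)
    n2 <- density_map(array(rnorm(48^3), c(48, 48, 48)), angpix)
  })
  fn <- fsc_curve(n1, n2)
  expect_lt(abs(mean(fn$fsc)), 0.05)
  expect_gte(mean(abs(fn$fsc) <= 4 / sqrt(fn$n_voxels)), 0.99)
  expect_error(fsc_curve(map, density_map(array(0, c(32, 32, 32)), angpix)),
               "grids differ")
})

test_that("half-set FSC decays from one towards zero on noisy data", {
  angpix <- 4.5
  map <- blob_voxel_map(fixture_blobs(), 48, angpix)
  ps <- make_projection_set(map, 200, seed = 23, noise_sd = 2)
  halves <- reconstruct_halves(ps$images, ps$records, ctf_mode = "none",
                               seed = 24)
  f <- fsc_curve(halves$half1, halves$half2)
  expect_gt(mean(f$fsc[1:4]), 0.9)
  expect_lt(mean(utils::tail(f$fsc, 4)), 0.5)
  expect_true(all(table(halves$assignment) == 100))
})

test_that("resolution_at interpolates the threshold crossing", {
  curve <- tibble::tibble(shell = 1:10, freq = (1:10) / 100,
                          fsc = c(1, 1, 1, 1, 1, 1, 0.5, 0, 0, 0))
  # hand interpolation between shells 7 (0.5) and 8 (0.0):
  f_hand <- 0.07 + (0.5 - 0.143) / 0.5 * 0.01
  expect_equal(resolution_at(curve, 0.143), 1 / f_hand, tolerance = 1e-12)

  ones <- tibble::tibble(shell = 1:10, freq = (1:10) / 100, fsc = rep(1, 10))
  expect_equal(resolution_at(ones, 0.143, pixel_size = 2.5), 5) # Nyquist
  # threshold 1 on a curve below 1 reports the first shell
  low <- tibble::tibble(shell = 1:10, freq = (1:10) / 100, fsc = rep(0.9, 10))
  expect_equal(resolution_at(low, 1), 100)
})

test_that("Guinier B-factor estimation recovers a constructed decay", {
  n <- 64
  angpix <- 2
  withr::with_seed(21, {
    flat <- density_map(array(rnorm(n^3), c(n, n, n)), angpix)
  })
  b0 <- estimate_bfactor(flat)
  expect_lt(abs(b0$bfactor), 5)

  # impose exp(-B/4 s^2) amplitude decay with B = 200 A^2
  s <- localrec:::radius_grid(dim(flat$data)) / (n * angpix)
  f <- localrec:::fft3_centered(flat$data) * exp(-200 / 4 * s^2)
  decayed <- density_map(Re(localrec:::ifft3_centered(f)), angpix)
  b <- estimate_bfactor(decayed)
  expect_equal(b$bfactor, 200, tolerance = 10 / 200)

  # sharpening by the estimate flattens the spectrum again
  sharp <- sharpen_map(decayed, b$bfactor)
  expect_lt(abs(estimate_bfactor(sharp)$bfactor), 10)

  expect_error(estimate_bfactor(flat, fit_range = c(4.3, 4.0)),
               "fewer than 3 shells")

  g <- glance(b)
  expect_equal(g$bfactor, b$bfactor)
  expect_gt(g$r_squared, 0.8)
  expect_s3_class(tidy(b), "tbl_df")
})

test_that("lowpass filtering is soft, DC-preserving and band-selective", {
  n <- 64
  angpix <- 2
  withr::with_seed(22, {
    m <- density_map(array(rnorm(n^3), c(n, n, n)), angpix)
  })
  # at Nyquist a band-limited map passes almost unchanged
  blobs <- blob_voxel_map(fixture_blobs(), n, angpix)
  near <- lowpass_filter(blobs, 2 * angpix)
  expect_lt(rel_rms(near$data, blobs$data), 1e-3)
  expect_equal(mean(near$data), mean(blobs$data), tolerance = 1e-10)

  # a pure sinusoid beyond the cutoff is crushed
  ax <- seq_len(n) - 1
  wave <- array(rep(sin(2 * pi * 12 * ax / n), n * n), c(n, n, n))
  filt <- lowpass_filter(wave, resolution = n * angpix / 6, pixel_size = angpix)
  expect_lt(stats::sd(filt), stats::sd(wave) / 100)

  out <- lowpass_filter(m, 20)
  expect_equal(mean(out$data), mean(m$data), tolerance = 1e-10)
  expect_error(lowpass_filter(m, 3), "Nyquist")

  # FSC tidiers and plots
  f <- fsc_curve(m, m)
  expect_s3_class(tidy(f), "tbl_df")
  expect_equal(glance(f)$resolution, 2 * angpix)
  expect_s3_class(autoplot(f), "ggplot")
  expect_s3_class(autoplot(estimate_bfactor(m)), "ggplot")
})
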