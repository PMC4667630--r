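test_that("record counts follow orbit-stabilizer for many groups", {
  parts <- random_particles(3, 1.35, 21)
  cases <- list(
    list(sym = "C1", dir = c(0.3, 0.2, 0.93), sites = 1),
    list(sym = "C5", dir = c(0, 0, 1), sites = 1),
    list(sym = "C5", dir = c(1, 0, 0.5), sites = 5),
    list(sym = "T", dir = c(1, 1, 1), sites = 4),
    list(sym = "O", dir = c(1, 1, 0), sites = 12),
    list(sym = "O", dir = c(0.2, 0.5, 0.9), sites = 24),
    list(sym = "I", dir = c(1, 1, 1), sites = 20),
    list(sym = "I", dir = c(0, 1, (1 + sqrt(5)) / 2), sites = 12),
    list(sym = "I", dir = c(0.21, 0.52, 0.93), sites = 60)
  )
  for (cs in cases) {
    v <- subunit_vector(cs$dir, 100)
    r <- expand_subparticles(parts, cs$sym, v, image_size = 200, seed = 1)
    expect_equal(nrow(r), 3 * cs$sites, info = cs$sym)
    expect_equal(length(unique(r$site_index)), cs$sites, info = cs$sym)
    # "all" emits one record per group element regardless of merging
    ra <- expand_subparticles(parts, cs$sym, v, image_size = 200,
                              degenerate = "all")
    expect_equal(nrow(ra), 3 * point_group(cs$sym)$order, info = cs$sym)
  }
})

test_that("C1 expansion composes particle orientation with the vector rotation", {
  parts <- random_particles(5, 2, 31)
  v <- subunit_vector(c(0.4, -0.3, 0.87), 90)
  r <- expand_subparticles(parts, "C1", v, image_size = 128)
  for (i in 1:5) {
    mp <- euler_to_matrix(parts$rot[i], parts$tilt[i], parts$psi[i])
    want <- mp %*% vector_to_matrix(v)
    got <- euler_to_matrix(r$rot[i], r$tilt[i], r$psi[i])
    expect_lt(max(abs(got - want)), 1e-8)
    off <- as.numeric(mp %*% (90 * v$direction)) / 2 # A -> px
    expect_equal(r$center_x[i], 64 - parts$origin_x[i] + off[1], tolerance = 1e-9)
    expect_equal(r$z_height[i], off[3], tolerance = 1e-9)
  }
})

test_that("degenerate orientations are seeded, reproducible and uniform", {
  parts <- random_particles(10000, 1.35, 41)
  v <- subunit_vector(c(0, 0, 1), 100) # on the C3 axis: 3 degenerate copies
  r1 <- expand_subparticles(parts, "C3", v, image_size = 200, seed = 99)
  r2 <- expand_subparticles(parts, "C3", v, image_size = 200, seed = 99)
  expect_identical(r1$degen_index, r2$degen_index)
  r3 <- expand_subparticles(parts, "C3", v, image_size = 200, seed = 100)
  expect_false(identical(r1$degen_index, r3$degen_index))
  expect_equal(sort(unique(r1$degen_index)), 0:2)
  expect_true(all(r1$n_degen == 3))
  # equal frequencies: chi-squared test at alpha = 0.01
  counts <- table(factor(r1$degen_index, levels = 0:2))
  chi2 <- sum((counts - 10000 / 3)^2 / (10000 / 3))
  expect_lt(chi2, stats::qchisq(0.99, df = 2))
})

test_that("split_subpixel keeps the origin within half a pixel", {
  s <- split_subpixel(100)
  expect_identical(s$int, 100L)
  expect_identical(s$origin, 0)
  s <- split_subpixel(100.7)
  expect_identical(s$int, 101L)
  expect_equal(s$origin, 0.3)
  s <- split_subpixel(-3.4)
  expect_identical(s$int, -3L)
  expect_equal(s$origin, 0.4)
  # halves round away from zero
  expect_identical(split_subpixel(2.5)$int, 3L)
  expect_identical(split_subpixel(-2.5)$int, -3L)
  withr::with_seed(12, {
    x <- runif(1000, -500, 500)
    s <- split_subpixel(x)
    expect_true(all(abs(s$origin) <= 0.5))
    expect_equal(s$int - s$origin, x, tolerance = 1e-12)
  })
})

test_that("extracting at the integer pixel and shifting by the origin re-centers", {
  n <- 64
  angpix <- 2
  withr::with_seed(13, {
    for (i in 1:5) {
      true_pos <- c(runif(1, 20, 40), runif(1, 20, 40)) # 0-based px
      ax <- seq_len(n) - 1
      img <- outer(exp(-(ax - true_pos[1])^2 / (2 * 2.5^2)),
                   exp(-(ax - true_pos[2])^2 / (2 * 2.5^2)))
      sx <- split_subpixel(true_pos[1])
      sy <- split_subpixel(true_pos[2])
      box <- 24
      xs <- (sx$int - box / 2):(sx$int + box / 2 - 1) + 1
      ys <- (sy$int - box / 2):(sy$int + box / 2 - 1) + 1
      win <- localrec:::shift_image(img[xs, ys], c(sx$origin, sy$origin))
      com <- center_of_mass(pmax(win, 0))
      expect_lt(max(abs(com - box / 2)), 0.05)
    }
  })
})

test_that("defocus adjustment is linear in height with the pinned sign", {
  ctf <- tibble::tibble(defocus_u = 20000, defocus_v = 19500)
  expect_equal(adjust_defocus(ctf, 0, 1.35), ctf)
  a <- adjust_defocus(ctf, 100, 1.35)
  expect_equal(a$defocus_u, 20000 - 135)
  expect_equal(a$defocus_v, 19500 - 135)
  expect_equal(adjust_defocus(ctf, 100, 1.35, invert_z = TRUE)$defocus_u,
               20000 + 135)
  # additivity
  expect_equal(adjust_defocus(adjust_defocus(ctf, 40, 1.35), -15, 1.35),
               adjust_defocus(ctf, 25, 1.35))
})

test_that("side-view selection keeps the sin(angle) solid-angle band", {
  expect_equal(nrow(filter_side_views(
    expand_subparticles(random_particles(50, 2, 51), "C1",
                        subunit_vector(c(0, 0, 1), 100), 128),
    side_max_angle = 90)), 50)

  # a vector along the beam is a pure top view
  top <- tibble::tibble(elevation = 90)
  expect_equal(nrow(filter_side_views(top, side_max_angle = 25)), 0)
  expect_equal(nrow(filter_side_views(tibble::tibble(elevation = 3),
                                      side_max_angle = 25)), 1)

  # Monte-Carlo: over uniform orientations the kept fraction is sin(25 deg)
  parts <- random_particles(10000, 2, 61)
  r <- expand_subparticles(parts, "C1", subunit_vector(c(0, 0, 1), 100), 128)
  kept <- nrow(filter_side_views(r, side_max_angle = 25)) / nrow(r)
  p <- sin(25 * pi / 180)
  expect_lt(abs(kept - p), 3 * sqrt(p * (1 - p) / 10000))

  # top-view exclusion removes the cos-cap fraction 1 - sin(65 deg)
  kept_top <- nrow(filter_side_views(r, side_max_angle = NULL,
                                     exclude_top_views = TRUE,
                                     top_angle = 25)) / nrow(r)
  p_top <- sin(65 * pi / 180)
  expect_lt(abs(kept_top - p_top), 3 * sqrt(p_top * (1 - p_top) / 10000))
})

test_that("overlap exclusion matches a brute-force all-pairs oracle", {
  parts <- random_particles(30, 2.78, 71)
  v <- subunit_vector(c(1, 1, 0), 280)
  r <- expand_subparticles(parts, "O", v, image_size = 288, seed = 3)

  # nothing removed at max_overlap = box_size
  expect_equal(nrow(filter_overlaps(r, 120, 120)), nrow(r))

  # duplicate centers: both removed
  dup <- r[r$parent_id == 1, ][c(1, 1), ]
  dup$subparticle_id <- 1:2
  expect_equal(nrow(filter_overlaps(dup, 60, 120)), 0)

  # brute-force oracle
  box <- 120
  max_ov <- 70
  keep_oracle <- rep(TRUE, nrow(r))
  for (i in seq_len(nrow(r))) {
    for (j in seq_len(nrow(r))) {
      if (i == j || r$parent_id[i] != r$parent_id[j]) next
      d <- sqrt((r$center_x[i] - r$center_x[j])^2 +
                  (r$center_y[i] - r$center_y[j])^2)
      if (box - d > max_ov) keep_oracle[i] <- FALSE
    }
  }
  got <- filter_overlaps(r, max_ov, box)
  expect_identical(sort(got$subparticle_id), sort(r$subparticle_id[keep_oracle]))

  # one-sided removal keeps at least as many records
  one <- filter_overlaps(r, max_ov, box, remove = "one")
  expect_gte(nrow(one), nrow(got))

  # filters commute when the overlap predicate is evaluated on the
  # full expansion (pure predicates of the particle geometry)
  a <- filter_overlaps(filter_side_views(r, 40), max_ov, box, reference = r)
  b <- filter_side_views(filter_overlaps(r, max_ov, box), 40)
  expect_identical(a$subparticle_id, b$subparticle_id)
})

test_that("extraction windows, skipping and normalization behave", {
  n <- 64
  img <- matrix(0, n, n)
  img[41, 29] <- 1 # 0-based (40, 28)
  stack <- image_stack(array(img, c(n, n, 1)), 2)
  rec <- tibble::tibble(parent_id = 1L, coord_x = 40L, coord_y = 28L,
                        origin_x = 0, origin_y = 0, pixel_size = 2)
  ex <- extract_subparticles(stack, rec, 16)
  expect_equal(ex$n_skipped, 0)
  expect_equal(which(ex$stack$data[, , 1] == 1, arr.ind = TRUE),
               matrix(c(9L, 9L), 1, dimnames = list(NULL, c("row", "col"))))

  # window past the edge is skipped and counted
  rec2 <- tibble::tibble(parent_id = 1L, coord_x = c(40L, 60L),
                         coord_y = c(28L, 60L),
                         origin_x = 0, origin_y = 0, pixel_size = 2)
  expect_message(ex2 <- extract_subparticles(stack, rec2, 16), "skipped")
  expect_equal(ex2$n_skipped, 1)
  expect_equal(dim(ex2$stack$data)[3], 1)

  # annulus normalization: zero mean and unit sd over the background
  withr::with_seed(14, {
    noisy <- image_stack(array(rnorm(n * n, 5, 3), c(n, n, 1)), 2)
  })
  ex3 <- extract_subparticles(noisy, rec, 32, normalize = TRUE)
  b <- 32
  r_g <- localrec:::radius_grid(c(b, b))
  bg <- r_g > 0.4 * b
  expect_lt(abs(mean(ex3$stack$data[, , 1][bg])), 1e-10)
  expect_equal(stats::sd(ex3$stack$data[, , 1][bg]), 1, tolerance = 1e-10)
})

test_that("occupancy summary reproduces the counting arithmetic", {
  s <- occupancy_summary(c(14721, 13912, 14583, 28078),
                         c(TRUE, TRUE, TRUE, FALSE), 20)
  expect_equal(s$percent_occupied, 60)
  expect_equal(s$copies_per_particle, 12)
  expect_equal(occupancy_summary(c(10, 20), c(TRUE, TRUE), 12)$percent_occupied, 100)
  expect_equal(occupancy_summary(c(10, 20), c(TRUE, TRUE), 12)$copies_per_particle, 12)
  none <- occupancy_summary(c(0, 30), c(TRUE, FALSE), 12)
  expect_equal(none$percent_occupied, 0)
  expect_equal(none$copies_per_particle, 0)
  expect_error(occupancy_summary(c(0, 0), c(TRUE, FALSE), 12), "undefined")
})
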