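#' Reconstruct a 3D map from sub-particle images by direct Fourier inversion
#'
#' Each image is re-centered by its origin (as a Fourier phase ramp),
#' CTF-premultiplied, and its 2D transform inserted as a central slice
#' into a 2x-oversampled 3D Fourier volume at the record's pose, with
#' trilinear spreading. CTF^2 weights are accumulated on the same grid
#' and the volume is divided by them with Wiener-style regularization
#' `F = N / (W + k * mean(W))`, which keeps the division stable where
#' the data are weak. In `phase_flip` mode the slices are multiplied by
#' `sign(CTF)` and weighted uniformly instead. Duplicating every input
#' image leaves the result unchanged.
#'
#' @param images An [image_stack()] (slices in record order) or 3D
#'   array.
#' @param records Tibble with one row per image: Euler angles,
#'   `origin_x`, `origin_y` and CTF columns (ignored when
#'   `ctf_mode = "none"`).
#' @param size Output map side length in pixels (defaults to the image
#'   size).
#' @param ctf_mode `"full"`, `"phase_flip"` or `"none"`.
#' @param pad Fourier oversampling factor.
#' @param wiener Wiener constant as a fraction of the mean accumulated
#'   weight.
#' @return A [density_map()].
#' @export
reconstruct_map <- function(images, records, size = NULL,
                            ctf_mode = c("full", "phase_flip", "none"),
                            pad = 2, wiener = 1e-3) {
  ctf_mode <- match.arg(ctf_mode)
  arr <- map_data(images)
  angpix <- if (inherits(images, "image_stack")) images$pixel_size else records$pixel_size[1]
  n_img <- dim(arr)[3]
  if (n_img == 0) stop("empty image stack", call. = FALSE)
  stopifnot(nrow(records) == n_img)
  n <- dim(arr)[1]
  if (is.null(size)) size <- n
  np <- pad * size
  dims <- as.integer(c(np, np, np))
  num_re <- array(0, dims); num_im <- array(0, dims); wt <- array(0, dims)
  for (i in seq_len(n_img)) {
    img <- pad_centered(arr[, , i], np)
    f2 <- fft2_centered(img)
    t_px <- c(records$origin_x[i], records$origin_y[i])
    if (any(t_px != 0)) f2 <- f2 * shift_phase2(np, t_px)
    if (ctf_mode == "none") {
      sw <- matrix(1, np, np)
    } else {
      h <- ctf_image(records[i, ], np, angpix)
      if (ctf_mode == "full") {
        f2 <- f2 * h
        sw <- h^2
      } else {
        f2 <- f2 * sign(h)
        sw <- matrix(1, np, np)
      }
    }
    m <- euler_to_matrix(records$rot[i], records$tilt[i], records$psi[i])
    .cpp_slice_insert(num_re, num_im, wt, dims,
                      matrix(complex(real = Re(f2), imaginary = Im(f2)), np, np),
                      sw, m, kb_insert$w, kb_insert$beta)
  }
  lambda <- wiener * mean(wt)
  f <- complex(real = num_re, imaginary = num_im) / (wt + lambda)
  dim(f) <- dims
  # weight-normalized insertion needs only the kernel's roll-off shape
  gw <- gridding_weights(np, 3, kb_insert)
  vol <- Re(ifft3_centered(f)) / (gw / gw[np / 2 + 1, np / 2 + 1, np / 2 + 1])
  density_map(crop_centered(vol, size), angpix)
}

#' Split records into gold-standard half-sets and reconstruct both
#'
#' @inheritParams reconstruct_map
#' @param seed Seed for the random split.
#' @return A list with `half1`, `half2` (maps) and `assignment`.
#' @export
reconstruct_halves <- function(images, records, size = NULL,
                               ctf_mode = "full", pad = 2, wiener = 1e-3,
                               seed = NULL) {
  arr <- map_data(images)
  n_img <- dim(arr)[3]
  half <- if (is.null(seed)) {
    sample(rep(c(1L, 2L), length.out = n_img))
  } else {
    withr::with_seed(seed, sample(rep(c(1L, 2L), length.out = n_img)))
  }
  angpix <- if (inherits(images, "image_stack")) images$pixel_size else records$pixel_size[1]
  rec <- function(k) {
    idx <- which(half == k)
    reconstruct_map(image_stack(arr[, , idx, drop = FALSE], angpix),
                    records[idx, ], size = size, ctf_mode = ctf_mode,
                    pad = pad, wiener = wiener)
  }
  list(half1 = rec(1L), half2 = rec(2L), assignment = half)
}
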