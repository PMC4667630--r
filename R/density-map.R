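#' Density maps and image stacks
#'
#' A `density_map` is a cubic, even-sized 3D voxel grid with a pixel
#' size in Angstrom per pixel. The real-space center is the voxel at
#' 0-based index `floor(N/2)` along each axis, which for the even grids
#' used here is `N/2`. An `image_stack` holds `n` square images of the
#' same pixel size as a 3D array with the image index last.
#'
#' @param data 3D numeric array. For `density_map()` all three
#'   dimensions must be equal and even.
#' @param pixel_size Pixel size in Angstrom per pixel.
#' @return An object of class `density_map` or `image_stack`.
#' @export
density_map <- function(data, pixel_size) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  d <- dim(data)
  if (length(unique(d)) != 1 || d[1] %% 2 != 0) {
    stop("density_map must be cubic with even side length", call. = FALSE)
  }
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  structure(list(data = data, pixel_size = as.numeric(pixel_size)),
            class = "density_map")
}

#' @rdname density_map
#' @export
image_stack <- function(data, pixel_size) {
  if (length(dim(data)) == 2) data <- array(data, c(dim(data), 1))
  stopifnot(is.array(data), length(dim(data)) == 3)
  d <- dim(data)
  if (d[1] != d[2]) stop("image_stack images must be square", call. = FALSE)
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  structure(list(data = data, pixel_size = as.numeric(pixel_size)),
            class = "image_stack")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_map> %d x %d x %d voxels, %.3f A/px [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$pixel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d images of %d x %d px, %.3f A/px\n",
              d[3], d[1], d[2], x$pixel_size))
  invisible(x)
}

map_data <- function(x) if (inherits(x, c("density_map", "image_stack"))) x$data else x

# --- centered FFT helpers (even sizes only) ---------------------------------

# For even n, fftshift and ifftshift coincide: swap halves.
shift_index <- function(n) c((n / 2 + 1):n, 1:(n / 2))

fftshift2 <- function(x) {
  n1 <- dim(x)[1]; n2 <- dim(x)[2]
  x[shift_index(n1), shift_index(n2)]
}

fftshift3 <- function(x) {
  d <- dim(x)
  x[shift_index(d[1]), shift_index(d[2]), shift_index(d[3])]
}

# Centered forward FFT: input with real-space center at index n/2
# (0-based); output spectrum with DC at index n/2, phases referenced to
# the real-space center.
fft2_centered <- function(x) fftshift2(stats::fft(fftshift2(x)))
fft3_centered <- function(x) fftshift3(stats::fft(fftshift3(x)))

ifft2_centered <- function(x) {
  n <- length(x)
  fftshift2(stats::fft(fftshift2(x), inverse = TRUE)) / n
}

ifft3_centered <- function(x) {
  n <- length(x)
  fftshift3(stats::fft(fftshift3(x), inverse = TRUE)) / n
}

# Zero-pad a centered square/cubic array to side `nout`, keeping the
# center voxel at the new center.
pad_centered <- function(x, nout) {
  d <- dim(x)
  n <- d[1]
  if (nout == n) return(x)
  stopifnot(nout > n, nout %% 2 == 0, n %% 2 == 0)
  off <- nout / 2 - n / 2
  idx <- (off + 1):(off + n)
  if (length(d) == 2) {
    out <- array(0, c(nout, nout))
    out[idx, idx] <- x
  } else {
    out <- array(0, c(nout, nout, nout))
    out[idx, idx, idx] <- x
  }
  out
}

crop_centered <- function(x, nout) {
  d <- dim(x)
  n <- d[1]
  if (nout == n) return(x)
  stopifnot(nout < n)
  off <- n / 2 - nout / 2
  idx <- (off + 1):(off + nout)
  if (length(d) == 2) x[idx, idx] else x[idx, idx, idx]
}

# Centered frequency index grids (cycles per grid length).
freq_grid2 <- function(n) {
  f <- seq_len(n) - 1 - n / 2
  list(kx = matrix(f, n, n), ky = matrix(f, n, n, byrow = TRUE))
}

# Radial |k| (in index units) for a centered 2D/3D grid.
radius_grid <- function(dims) {
  gr <- lapply(dims, function(n) seq_len(n) - 1 - n / 2)
  if (length(dims) == 2) {
    sqrt(outer(gr[[1]]^2, gr[[2]]^2, "+"))
  } else {
    r2 <- outer(outer(gr[[1]]^2, gr[[2]]^2, "+"), gr[[3]]^2, "+")
    sqrt(r2)
  }
}

# Kaiser-Bessel gridding parameters (Beatty shape factors for 2x
# oversampling): width-6 kernel for slice extraction, where projection
# accuracy matters most, and a cheaper width-4 kernel for slice
# insertion during reconstruction.
kb_extract <- list(w = 6, beta = 13.8551003461248)
kb_insert <- list(w = 4, beta = 8.99615229356044)

# Gridding correction for Kaiser-Bessel interpolation in Fourier space:
# convolution-sampling the DFT with the kernel multiplies real space by
# the kernel's continuous transform per axis; dividing it out
# beforehand (extraction) or afterwards (insertion) compensates.
gridding_weights <- function(n, ndim, kb = kb_extract) {
  kb_w <- kb$w; kb_beta <- kb$beta
  nu <- (seq_len(n) - 1 - n / 2) / n
  s2 <- kb_beta^2 - (pi * kb_w * nu)^2
  w1 <- ifelse(s2 > 0,
               kb_w * sinh(sqrt(pmax(s2, 0))) / sqrt(pmax(s2, 1e-300)),
               kb_w * sin(sqrt(pmax(-s2, 1e-300))) / sqrt(pmax(-s2, 1e-300)))
  if (ndim == 2) outer(w1, w1) else outer(outer(w1, w1), w1)
}

# Phase ramp that translates an image by t = c(tx, ty) pixels:
# multiply the centered spectrum elementwise.
shift_phase2 <- function(n, t) {
  g <- freq_grid2(n)
  exp(-2i * pi * (g$kx * t[1] + g$ky * t[2]) / n)
}
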