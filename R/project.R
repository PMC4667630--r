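#' Project a density map in a particle's orientation
#'
#' Computes the orthographic line integral of the map along the beam
#' after rotating it by the pose, i.e. the projection image in which a
#' map point `p` lands at the image position `(M %*% p)[1:2]`. The
#' projector extracts the central slice of the map's 3D Fourier
#' transform (2x zero-padded for oversampling, trilinear interpolation)
#' and inverse-transforms it. The result is translated by `-origin`, so
#' it matches a raw particle image whose alignment origin is `origin`
#' (shifting that image *by* its origin re-centers it).
#'
#' When many poses are projected from one map, build the padded
#' transform once with `fourier_projector()` and call `project_slice()`
#' per pose.
#'
#' @param map A [density_map()].
#' @param euler Numeric `c(rot, tilt, psi)` in degrees, or a 3x3
#'   rotation matrix.
#' @param origin Alignment origin `c(x, y)` in pixels.
#' @param pad Oversampling factor for the Fourier transform.
#' @return A numeric `N x N` projection image.
#' @export
project_map <- function(map, euler, origin = c(0, 0), pad = 2) {
  project_slice(fourier_projector(map, pad), euler, origin)
}

#' @rdname project_map
#' @export
fourier_projector <- function(map, pad = 2) {
  stopifnot(inherits(map, "density_map"))
  n <- dim(map$data)[1]
  np <- pad * n
  padded <- pad_centered(map$data, np) / gridding_weights(np, 3, kb_extract)
  f3 <- fft3_centered(padded)
  structure(list(re = Re(f3), im = Im(f3), n = n, np = np,
                 pixel_size = map$pixel_size),
            class = "fourier_projector")
}

#' @rdname project_map
#' @param projector A `fourier_projector` object.
#' @export
project_slice <- function(projector, euler, origin = c(0, 0)) {
  m <- if (is.matrix(euler)) euler else euler_to_matrix(euler[1], euler[2], euler[3])
  np <- projector$np
  s <- .cpp_slice_sample(projector$re, projector$im, as.integer(c(np, np, np)),
                         m, as.integer(np), kb_extract$w, kb_extract$beta)
  t_px <- -as.numeric(origin)
  if (any(t_px != 0)) s <- s * shift_phase2(np, t_px)
  img <- Re(ifft2_centered(s))
  crop_centered(img, projector$n)
}

# Translate an image by t pixels (Fourier phase ramp).
shift_image <- function(image, t) {
  n <- dim(image)[1]
  Re(ifft2_centered(fft2_centered(image) * shift_phase2(n, t)))
}

#' Low-pass filter a map or image
#'
#' Soft radial cutoff at `1/resolution` with a cosine edge
#' (`edge_width` Fourier pixels wide, ending at the cutoff); the DC
#' component is preserved exactly.
#'
#' @param x A [density_map()], [image_stack()] image (matrix), or plain
#'   array.
#' @param resolution Cutoff resolution in Angstrom; must be at least
#'   twice the pixel size (Nyquist).
#' @param pixel_size Angstrom per pixel (taken from `x` when it carries
#'   one).
#' @param edge_width Cosine edge width in Fourier pixels.
#' @return The filtered object, same kind as the input.
#' @export
lowpass_filter <- function(x, resolution, pixel_size = NULL, edge_width = 3) {
  if (inherits(x, "density_map")) {
    out <- x
    out$data <- lowpass_filter(x$data, resolution, x$pixel_size, edge_width)
    return(out)
  }
  stopifnot(!is.null(pixel_size))
  d <- dim(x)
  n <- d[1]
  if (resolution < 2 * pixel_size) {
    stop("resolution ", resolution, " A is beyond Nyquist (", 2 * pixel_size,
         " A)", call. = FALSE)
  }
  r <- radius_grid(d)
  rc <- n * pixel_size / resolution # cutoff radius in Fourier pixels
  gain <- ifelse(r <= rc - edge_width, 1,
                 ifelse(r > rc, 0,
                        0.5 * (1 + cos(pi * (r - (rc - edge_width)) / edge_width))))
  gain[r == 0] <- 1
  f <- if (length(d) == 3) {
    Re(ifft3_centered(fft3_centered(x) * gain))
  } else {
    Re(ifft2_centered(fft2_centered(x) * gain))
  }
  f
}
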