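#' Fourier shell correlation between two maps
#'
#' Computes the normalized cross-correlation of the two maps' Fourier
#' coefficients in shells one Fourier voxel wide, the standard
#' agreement measure between reconstructions from two independent
#' half-sets. An optional real-space mask is applied to both maps
#' first.
#'
#' @param half_a,half_b Two [density_map()]s on the same grid.
#' @param mask Optional [density_map()] mask (values in `[0, 1]`).
#' @return An object of class `fsc_curve`: a tibble with columns
#'   `shell` (Fourier voxel radius), `freq` (1/Angstrom) and `fsc`,
#'   with the pixel size as an attribute.
#' @export
fsc_curve <- function(half_a, half_b, mask = NULL) {
  stopifnot(inherits(half_a, "density_map"), inherits(half_b, "density_map"))
  if (!all(dim(half_a$data) == dim(half_b$data))) {
    stop("map grids differ", call. = FALSE)
  }
  a <- half_a$data
  b <- half_b$data
  if (!is.null(mask)) {
    if (!all(dim(mask$data) == dim(a))) stop("mask grid differs", call. = FALSE)
    a <- a * mask$data
    b <- b * mask$data
  }
  n <- dim(a)[1]
  fa <- fft3_centered(a)
  fb <- fft3_centered(b)
  shell <- round(radius_grid(dim(a)))
  keep <- shell >= 1 & shell <= n / 2 - 1
  sh <- as.integer(shell[keep])
  cross <- Re(fa[keep] * Conj(fb[keep]))
  pa <- Mod(fa[keep])^2
  pb <- Mod(fb[keep])^2
  num <- tapply(cross, sh, sum)
  da <- tapply(pa, sh, sum)
  db <- tapply(pb, sh, sum)
  nvox <- tabulate(sh, nbins = max(sh))[sort(unique(sh))]
  shells <- as.integer(names(num))
  denom <- sqrt(da * db)
  out <- tibble::tibble(
    shell = shells,
    freq = shells / (n * half_a$pixel_size),
    fsc = ifelse(denom > 0, as.numeric(num / denom), 0),
    n_voxels = as.integer(nvox)
  )
  structure(out, class = c("fsc_curve", class(out)),
            pixel_size = half_a$pixel_size, n = n)
}

#' Resolution at an FSC threshold
#'
#' Reports the resolution at which the FSC first drops below the
#' threshold (0.143 for independent half-set reconstructions), linearly
#' interpolating the crossing frequency between shells. A curve that
#' never crosses reports Nyquist (twice the pixel size).
#'
#' @param curve An [fsc_curve()] (or a data frame with `freq` and
#'   `fsc`).
#' @param threshold FSC threshold.
#' @param pixel_size Required if `curve` carries no pixel-size
#'   attribute.
#' @return Resolution in Angstrom.
#' @export
resolution_at <- function(curve, threshold = 0.143, pixel_size = NULL) {
  stopifnot(nrow(curve) > 0)
  ps <- attr(curve, "pixel_size") %||% pixel_size
  freq <- c(0, curve$freq)
  fsc <- c(1, curve$fsc)
  below <- which(fsc < threshold)
  if (length(below) == 0) {
    if (is.null(ps)) stop("pixel_size needed to report Nyquist", call. = FALSE)
    return(2 * ps)
  }
  i <- below[1]
  if (i <= 2) return(1 / curve$freq[1]) # crosses at/before the first shell
  f_cross <- freq[i - 1] +
    (fsc[i - 1] - threshold) / (fsc[i - 1] - fsc[i]) * (freq[i] - freq[i - 1])
  1 / f_cross
}

# Spherically averaged Fourier amplitude per shell.
shell_amplitudes <- function(map) {
  arr <- map_data(map)
  n <- dim(arr)[1]
  f <- fft3_centered(arr)
  shell <- round(radius_grid(dim(arr)))
  keep <- shell >= 1 & shell <= n / 2 - 1
  sh <- as.integer(shell[keep])
  amp <- tapply(Mod(f[keep]), sh, mean)
  shells <- as.integer(names(amp))
  tibble::tibble(shell = shells,
                 freq = shells / (n * map$pixel_size),
                 amplitude = as.numeric(amp))
}

#' Estimate the B-factor of a map by a Guinier fit
#'
#' Fits `ln(amplitude) = const - (B/4) * s^2` by least squares to the
#' spherically averaged structure-factor amplitudes over the resolution
#' range `fit_range` (Angstrom, low to high), the classic Guinier
#' analysis of amplitude decay. The returned B-factor (Angstrom^2) is
#' `-4 * slope`.
#'
#' @param map A [density_map()].
#' @param fit_range Resolution range `c(low, high)` in Angstrom;
#'   defaults to `max(10, 5 * pixel_size)` down to 2.5x the pixel size.
#' @return An object of class `guinier_fit` with elements `bfactor`,
#'   `fit` (per-shell tibble) and `model` (the `lm` fit).
#' @export
estimate_bfactor <- function(map, fit_range = NULL) {
  stopifnot(inherits(map, "density_map"))
  if (is.null(fit_range)) {
    fit_range <- c(max(10, 5 * map$pixel_size), 2.5 * map$pixel_size)
  }
  lo <- max(fit_range); hi <- min(fit_range) # resolutions, A
  amps <- shell_amplitudes(map)
  sel <- amps$freq >= 1 / lo & amps$freq <= 1 / hi & amps$amplitude > 0
  if (sum(sel) < 3) {
    stop("fewer than 3 shells in the Guinier fit range", call. = FALSE)
  }
  d <- dplyr::mutate(amps[sel, ], s2 = .data$freq^2, log_amp = log(.data$amplitude))
  fit <- stats::lm(log_amp ~ s2, data = d)
  structure(list(bfactor = -4 * unname(stats::coef(fit)[2]),
                 fit = d, model = fit, fit_range = c(lo, hi)),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit> B = %.1f A^2 over %.1f-%.1f A (%d shells)\n",
              x$bfactor, x$fit_range[1], x$fit_range[2], nrow(x$fit)))
  invisible(x)
}

#' Sharpen a map by an inverse B-factor
#'
#' Multiplies the Fourier amplitudes by `exp(+B/4 * s^2)`, undoing the
#' Gaussian amplitude falloff measured by [estimate_bfactor()].
#'
#' @param map A [density_map()].
#' @param bfactor B-factor in Angstrom^2 (positive sharpens).
#' @return The sharpened [density_map()].
#' @export
sharpen_map <- function(map, bfactor) {
  stopifnot(inherits(map, "density_map"))
  arr <- map$data
  n <- dim(arr)[1]
  s <- radius_grid(dim(arr)) / (n * map$pixel_size)
  f <- fft3_centered(arr) * exp(bfactor / 4 * s^2)
  density_map(Re(ifft3_centered(f)), map$pixel_size)
}
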