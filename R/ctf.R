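#' Contrast transfer function
#'
#' Evaluates the microscope CTF
#' `CTF(s, theta) = -(sqrt(1 - A^2) * sin(chi) + A * cos(chi))` with
#' phase aberration
#' `chi = pi * lambda * dz(theta) * s^2 - (pi/2) * Cs * lambda^3 * s^4`,
#' astigmatic defocus
#' `dz(theta) = (du + dv)/2 + (du - dv)/2 * cos(2 * (theta - astig))`
#' and the relativistic electron wavelength from the acceleration
#' voltage. Positive defocus denotes underfocus.
#'
#' @param ctf A list or one-row data frame with `defocus_u`,
#'   `defocus_v` (Angstrom), `astig_angle` (degrees), `voltage` (kV),
#'   `cs` (mm), `amplitude_contrast` (fraction).
#' @param spatial_freq Spatial frequency in 1/Angstrom (vectorized).
#' @param azimuth Azimuth in degrees (vectorized).
#' @return CTF values in `[-1, 1]`; at `s = 0` the value is `-A`.
#' @examples
#' ctf <- list(defocus_u = 15000, defocus_v = 15000, astig_angle = 0,
#'             voltage = 300, cs = 2, amplitude_contrast = 0.07)
#' ctf_evaluate(ctf, c(0, 0.02, 0.05), 0)
#' @export
ctf_evaluate <- function(ctf, spatial_freq, azimuth = 0) {
  lambda <- electron_wavelength(ctf$voltage)
  a <- ctf$amplitude_contrast
  dz <- (ctf$defocus_u + ctf$defocus_v) / 2 +
    (ctf$defocus_u - ctf$defocus_v) / 2 *
      cos(2 * (azimuth - ctf$astig_angle) * pi / 180)
  cs_ang <- ctf$cs * 1e7 # mm -> Angstrom
  chi <- pi * lambda * dz * spatial_freq^2 -
    (pi / 2) * cs_ang * lambda^3 * spatial_freq^4
  -(sqrt(1 - a^2) * sin(chi) + a * cos(chi))
}

# Relativistic electron wavelength (Angstrom) for voltage in kV.
electron_wavelength <- function(voltage_kv) {
  stopifnot(voltage_kv > 0)
  v <- voltage_kv * 1e3
  12.2643 / sqrt(v * (1 + v * 0.978466e-6))
}

# Centered n x n array of CTF values for an image of given pixel size.
ctf_image <- function(ctf, n, pixel_size) {
  g <- freq_grid2(n)
  s <- sqrt(g$kx^2 + g$ky^2) / (n * pixel_size)
  theta <- atan2(g$ky, g$kx) * 180 / pi
  ctf_evaluate(ctf, s, theta)
}

#' Apply (or phase-flip) the CTF to an image
#'
#' Multiplies the image's Fourier transform by the CTF (`mode =
#' "full"`) or by its sign only (`mode = "phase_flip"`, which corrects
#' the contrast inversions while preserving every Fourier amplitude).
#'
#' @param image Numeric matrix (square, even side).
#' @param ctf CTF parameters as in [ctf_evaluate()].
#' @param pixel_size Angstrom per pixel.
#' @param mode `"full"` or `"phase_flip"`.
#' @return The modulated image (numeric matrix).
#' @export
apply_ctf <- function(image, ctf, pixel_size, mode = c("full", "phase_flip")) {
  mode <- match.arg(mode)
  n <- dim(image)[1]
  stopifnot(dim(image)[2] == n, n %% 2 == 0)
  h <- ctf_image(ctf, n, pixel_size)
  if (mode == "phase_flip") h <- sign(h)
  Re(ifft2_centered(fft2_centered(image) * h))
}
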