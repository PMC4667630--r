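#' Tidiers and plots for FSC curves and Guinier fits
#'
#' `tidy()` returns the per-shell table; `glance()` the one-row
#' summary; `autoplot()` a ggplot of the curve or fit.
#'
#' @param x An `fsc_curve` or `guinier_fit` object.
#' @param ... Unused.
#' @name localrec-tidiers
NULL

#' @rdname localrec-tidiers
#' @export
tidy.fsc_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("shell", "freq", "fsc", "n_voxels")])
}

#' @rdname localrec-tidiers
#' @param threshold FSC threshold for the reported resolution.
#' @export
glance.fsc_curve <- function(x, threshold = 0.143, ...) {
  tibble::tibble(
    resolution = resolution_at(x, threshold),
    threshold = threshold,
    n_shells = nrow(x),
    pixel_size = attr(x, "pixel_size")
  )
}

#' @rdname localrec-tidiers
#' @param object An `fsc_curve` object.
#' @export
autoplot.fsc_curve <- function(object, threshold = 0.143, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$fsc)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "spatial frequency (1/Å)", y = "FSC") +
    ggplot2::ylim(min(0, min(df$fsc)), 1)
}

#' @rdname localrec-tidiers
#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble::as_tibble(x$fit)
}

#' @rdname localrec-tidiers
#' @export
glance.guinier_fit <- function(x, ...) {
  tibble::tibble(
    bfactor = x$bfactor,
    r_squared = summary(x$model)$r.squared,
    n_shells = nrow(x$fit),
    fit_low = x$fit_range[1],
    fit_high = x$fit_range[2]
  )
}

#' @rdname localrec-tidiers
#' @export
autoplot.guinier_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s2, y = .data$log_amp)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = expression(s^2 ~ (ring(A)^-2)),
                  y = "ln mean |F|",
                  subtitle = sprintf("B = %.0f Å²", object$bfactor))
}

#' Plot sub-particle positions on the particle image plane
#'
#' A quick diagnostic: the in-plane sub-particle centers of a few
#' particles, colored by elevation (side views near zero).
#'
#' @param records Sub-particle records from [expand_subparticles()].
#' @param particles Particle ids to show (default first 4).
#' @return A ggplot object.
#' @export
plot_subparticle_positions <- function(records, particles = NULL) {
  if (is.null(particles)) {
    particles <- utils::head(unique(records$parent_id), 4)
  }
  df <- records[records$parent_id %in% particles, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center_x, y = .data$center_y,
                                   colour = abs(.data$elevation))) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parent_id) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "|elevation| (°)")
}
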