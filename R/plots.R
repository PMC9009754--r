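#' Plot methods
#'
#' `autoplot()` methods for the package's result types: spectra, wavelet
#' decompositions (vertically offset per-level coefficients), level profiles
#' (total-variation versus energy fractions) and identification results
#' (input derivative, shrunk reconstruction and called peaks).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name thz-autoplot
NULL

#' @rdname thz-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.thz_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$frequency, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (THz)",
                  y = switch(spectrum_kind(object),
                             reflectivity = expression("|" * rho * "|"^2),
                             derivative = expression(-d * "|" * rho * "|"^2 / df),
                             "value")) +
    ggplot2::theme_minimal()
}

#' @rdname thz-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.thz_modwt <- function(object, ...) {
  tab <- tidy(object)
  tab <- tab[tab$component == "wavelet", ]
  # min-max normalise per level for display only, then offset vertically
  tab <- dplyr::mutate(
    dplyr::group_by(tab, .data$level),
    shown = (.data$coefficient - min(.data$coefficient)) /
      max(1e-300, diff(range(.data$coefficient))) + .data$level)
  xcol <- if ("frequency" %in% names(tab)) "frequency" else "index"
  ggplot2::ggplot(tab, ggplot2::aes(x = .data[[xcol]], y = .data$shown,
                                    group = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (xcol == "frequency") "Frequency (THz)" else "Index",
                  y = "Wavelet coefficients (offset per level)") +
    ggplot2::theme_minimal()
}

#' @rdname thz-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.thz_level_profile <- function(object, ...) {
  tab <- tidyr_longer(as_tibble(object))
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$level), y = .data$fraction,
                                    fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Decomposition level", y = "Fraction of total",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

# small local pivot to avoid a tidyr dependency for one reshape
tidyr_longer <- function(tab) {
  tibble(level = rep(tab$level, 2),
         measure = rep(c("TV2", "energy"), each = nrow(tab)),
         fraction = c(tab$tv2_fraction, tab$energy_fraction))
}

#' @rdname thz-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.thz_identification <- function(object, ...) {
  tab <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(object$derivative), signal = "derivative"),
    dplyr::mutate(as_tibble(object$reconstructed), signal = "reconstructed"))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$frequency, y = .data$value,
                                         colour = .data$signal)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Frequency (THz)",
                  y = expression(-d * "|" * rho * "|"^2 / df), colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(object$peaks))
    p <- p + ggplot2::geom_vline(xintercept = object$peaks$frequency,
                                 linetype = "dashed", alpha = 0.5)
  p
}
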