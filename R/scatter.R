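#' Kirchhoff-approximation specular roll-off
#'
#' Under the Kirchhoff (tangent-plane) approximation, the specular power
#' reflectivity of a rough surface with Gaussian height statistics decays
#' with the Rayleigh factor:
#' \deqn{|\rho(f)|^2 = |r|^2 \exp(-4 k^2 \sigma^2 \cos^2\theta_i),}
#' with \eqn{k = 2\pi f / c} the free-space wavenumber, \eqn{\sigma} the RMS
#' surface height and \eqn{\theta_i} the incidence angle from the surface
#' normal.
#'
#' @param frequency Frequency axis in THz (or a `thz_spectrum` whose axis is
#'   reused).
#' @param sigma_um RMS surface height in micrometres (>= 0).
#' @param theta_deg Incidence angle in degrees from the surface normal.
#' @param r2 Fresnel power reflectivity baseline \eqn{|r|^2} in (0, 1].
#' @param band Optional analysis band (THz).
#' @return A `thz_spectrum` of kind `"reflectivity"`.
#' @examples
#' rayleigh_factor(1.54, 15, 35)   # ~0.533
#' @export
kirchhoff_rolloff <- function(frequency, sigma_um, theta_deg = 35, r2 = 0.3,
                              band = NULL) {
  if (inherits(frequency, "data.frame")) frequency <- frequency$frequency
  stopifnot(sigma_um >= 0, theta_deg >= 0, theta_deg < 90, r2 > 0, r2 <= 1)
  thz_spectrum(frequency, r2 * rayleigh_factor(frequency, sigma_um, theta_deg),
               kind = "reflectivity", band = band)
}

#' @rdname kirchhoff_rolloff
#' @export
rayleigh_factor <- function(frequency, sigma_um, theta_deg) {
  k <- wavenumber(frequency)
  exp(-4 * k^2 * sigma_um^2 * cos(deg2rad(theta_deg))^2)
}

#' Estimate RMS surface roughness from a reflectivity spectrum
#'
#' Fits the Kirchhoff roll-off in the log domain, where it is exactly linear
#' in \eqn{k^2}: \eqn{\ln|\rho|^2 = \ln|r|^2 - 4\sigma^2\cos^2\theta_i\,k^2}.
#' Ordinary least squares on the band (after dropping samples below a
#' relative reflectivity floor, which would otherwise drag the fit into the
#' noise floor) yields \eqn{\hat\sigma = \sqrt{-\mathrm{slope}}/(2\cos\theta_i)}
#' and the baseline from the intercept.  A non-negative slope (no decay)
#' returns \eqn{\hat\sigma = 0} with a warning.
#'
#' @param s A `thz_spectrum` of kind `"reflectivity"`.
#' @param theta_deg Incidence angle in degrees.
#' @param fit_band Band used for the fit; defaults to the spectrum's band.
#' @param rel_floor Samples with reflectivity below `rel_floor` times the
#'   in-band maximum are excluded from the fit.
#' @return A `thz_kirchhoff_fit` object with elements `sigma_um`, `sigma_se`,
#'   `r2`, `slope`, `residual_rms`, `n`, `band`, `theta_deg`.  Supports
#'   [tidy()] and [glance()].
#' @export
fit_sigma <- function(s, theta_deg = 35, fit_band = NULL, rel_floor = 0.01) {
  if (!identical(spectrum_kind(s), "reflectivity"))
    stop_thz("`fit_sigma()` expects a reflectivity spectrum.", "thz_invalid_kind")
  band <- fit_band %||% spectrum_band(s)
  idx <- band_indices(s$frequency, band)
  f <- s$frequency[idx]
  p <- s$value[idx]
  keep <- p > rel_floor * max(p) & p > 0
  f <- f[keep]; p <- p[keep]
  if (length(f) < 4L)
    stop_thz("Too few usable samples in the fit band.", "thz_fit_error")
  k2 <- wavenumber(f)^2
  fit <- lm(log(p) ~ k2)
  slope <- unname(coef(fit)[2])
  # noiseless inputs fit exactly; summary.lm's perfect-fit warning is expected
  slope_se <- suppressWarnings(summary(fit))$coefficients[2, 2]
  ct <- cos(deg2rad(theta_deg))
  if (slope >= 0) {
    warn("Fitted slope is non-negative (no Rayleigh decay); returning sigma = 0.")
    sigma <- 0
    sigma_se <- NA_real_
  } else {
    sigma <- sqrt(-slope) / (2 * ct)
    # delta method: d sigma / d slope = -1 / (4 ct sqrt(-slope))
    sigma_se <- slope_se / (4 * ct * sqrt(-slope))
  }
  structure(list(sigma_um = sigma, sigma_se = sigma_se,
                 r2 = exp(unname(coef(fit)[1])), slope = slope,
                 slope_se = slope_se,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 n = length(f), band = band, theta_deg = theta_deg),
            class = "thz_kirchhoff_fit")
}

#' @export
print.thz_kirchhoff_fit <- function(x, ...) {
  cat("Kirchhoff roll-off fit\n")
  cat(sprintf("  sigma_um     : %.4g (se %.3g)\n", x$sigma_um, x$sigma_se))
  cat(sprintf("  r2 baseline  : %.4g\n", x$r2))
  cat(sprintf("  slope        : %.6g (ln|rho|^2 per (rad/um)^2)\n", x$slope))
  cat(sprintf("  residual RMS : %.3g\n", x$residual_rms))
  cat(sprintf("  band         : %.3g-%.3g THz (n = %d), theta_i = %g deg\n",
              x$band[1], x$band[2], x$n, x$theta_deg))
  invisible(x)
}

#' Fraunhofer roughness criterion
#'
#' The Fraunhofer criterion \eqn{\sigma \ge \lambda / (32 \cos\theta_i)}
#' defines the wavelength threshold \eqn{\lambda_{th} = 32\,\sigma\cos\theta_i}
#' below which (i.e. for frequencies above \eqn{f_{th} = c/\lambda_{th}})
#' rough-surface scattering significantly distorts the spectrum.
#'
#' @param sigma_um RMS surface height in micrometres.
#' @param theta_deg Incidence angle in degrees.
#' @return A one-row tibble with `lambda_um` and `freq_ghz`; a smooth surface
#'   (`sigma_um = 0`) has no finite threshold and returns `freq_ghz = Inf`.
#' @examples
#' fraunhofer_threshold(55, 0)    # ~170.3 GHz
#' @export
fraunhofer_threshold <- function(sigma_um, theta_deg = 35) {
  stopifnot(sigma_um >= 0)
  lambda <- 32 * sigma_um * cos(deg2rad(theta_deg))
  freq <- if (lambda > 0) .c_um_ghz / lambda else Inf
  tibble(lambda_um = lambda, freq_ghz = freq)
}
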