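#' Reference absorption line lists and roughness table
#'
#' `lactose_lines` and `paba_lines` hold the low-frequency resonant modes of
#' alpha-lactose monohydrate (0.53, 1.2, 1.38 THz) and 4-aminobenzoic acid
#' (0.6, 0.8, 1.29, 1.54 THz) with simulator default depths and widths; the
#' lactose 1.2 THz mode is deliberately the weakest and narrowest.
#' `water_lines` holds atmospheric water-vapour absorption lines across the
#' 0.2-1.8 THz band with strength-weighted dip depths (the 1.6-1.8 THz
#' cluster is close to saturation over metre-scale ambient paths).
#' `sandpaper_roughness` records, per sandpaper grit, the RMS surface height
#' (micrometres) fitted for each material together with the literature value
#' and the printed Fraunhofer frequency.
#'
#' @format Tibbles; line lists have columns `center` (THz), `depth`
#'   (fractional absorption at the line centre) and `fwhm` (THz).
#' @name line_lists
NULL

#' @rdname line_lists
#' @export
lactose_lines <- tibble::tibble(
  center = c(0.53, 1.20, 1.38),
  depth  = c(0.80, 0.15, 0.60),
  fwhm   = c(0.025, 0.015, 0.030))

#' @rdname line_lists
#' @export
paba_lines <- tibble::tibble(
  center = c(0.60, 0.80, 1.29, 1.54),
  depth  = c(0.50, 0.60, 0.50, 0.35),
  fwhm   = c(0.030, 0.030, 0.035, 0.040))

#' @rdname line_lists
#' @export
water_lines <- tibble::tibble(
  center = c(0.557, 0.752, 0.988, 1.097, 1.163, 1.411, 1.603, 1.669, 1.717, 1.762),
  depth  = c(0.35,  0.30,  0.45,  0.55,  0.60,  0.65,  0.80,  0.95,  0.95,  0.85),
  fwhm   = rep(0.005, 10))

#' @rdname line_lists
#' @export
sandpaper_roughness <- tibble::tibble(
  grit = c(220L, 120L, 80L, 40L),
  sigma_lactose_um = c(16, 26, 44, 93),
  sigma_paba_um = c(15, 22, 40, 91),
  sigma_literature_um = c(15, 21, 55, 135),
  fraunhofer_ghz = c(480, 300, 170, 80))

#' Define a synthetic measurement scenario
#'
#' A scenario bundles everything the simulator needs: the absorption line
#' list, the Kirchhoff roughness and geometry, the detection offset from the
#' specular angle, noise levels and the frequency grid.
#'
#' @param lines Tibble with columns `center` (THz), `depth` in (0,1) and
#'   `fwhm` (THz); may have zero rows.
#' @param sigma_um RMS surface height, micrometres.
#' @param theta_deg Incidence angle, degrees from the surface normal.
#' @param offset_deg Detection offset from the specular direction, degrees
#'   (0 = specular).
#' @param r2 Fresnel power-reflectivity baseline.
#' @param snr_db Measurement signal-to-noise ratio in dB (power);
#'   the relative noise standard deviation is `10^(-snr_db/10)`.
#'   Use `Inf` for a noiseless spectrum.
#' @param noise_floor Absolute reflectivity floor; defaults to `1e-3 * r2`.
#' @param water_vapor Include atmospheric water-vapour lines?
#' @param delta_f Frequency grid step, THz.
#' @param band Frequency band `(f1, f2)`, THz.
#' @param seed Integer seed making the generated spectrum deterministic.
#' @return A `thz_scenario` list.
#' @export
thz_scenario <- function(lines, sigma_um, theta_deg = 35, offset_deg = 0,
                         r2 = 0.3, snr_db = 30, noise_floor = 1e-3 * r2,
                         water_vapor = TRUE, delta_f = 0.005,
                         band = c(0.2, 1.8), seed = 1L) {
  stopifnot(delta_f > 0, band[1] < band[2], offset_deg >= 0, sigma_um >= 0)
  lines <- as_tibble(lines)
  if (nrow(lines)) {
    stopifnot(all(lines$depth > 0), all(lines$depth < 1), all(lines$fwhm > 0),
              all(lines$center >= band[1]), all(lines$center <= band[2]))
  }
  structure(list(lines = lines, sigma_um = sigma_um, theta_deg = theta_deg,
                 offset_deg = offset_deg, r2 = r2, snr_db = snr_db,
                 noise_floor = noise_floor, water_vapor = water_vapor,
                 delta_f = delta_f, band = band, seed = as.integer(seed)),
            class = "thz_scenario")
}

#' @export
print.thz_scenario <- function(x, ...) {
  cat(sprintf(
    "<thz_scenario: %d lines, sigma = %g um, theta_i = %g deg, offset = %g deg,\n  r2 = %g, SNR = %g dB, water %s, df = %g THz, band %.3g-%.3g THz, seed %d>\n",
    nrow(x$lines), x$sigma_um, x$theta_deg, x$offset_deg, x$r2, x$snr_db,
    if (x$water_vapor) "on" else "off", x$delta_f, x$band[1], x$band[2], x$seed))
  invisible(x)
}

# Gaussian off-specular collection lobe.  The angular width of the scattered
# energy collected at an offset from the specular direction shrinks with both
# frequency and roughness; it is modelled as w(f) = w_ref / (k sigma) degrees
# with w_ref = 5 degrees.  Identity at zero offset and for smooth surfaces.
# A heuristic emulation of off-specular energy/bandwidth loss, not a result
# of the Kirchhoff model.
angular_lobe <- function(f, sigma_um, offset_deg, w_ref = 5) {
  if (offset_deg <= 0 || sigma_um <= 0) return(rep(1, length(f)))
  w <- w_ref / (wavenumber(f) * sigma_um)
  exp(-offset_deg^2 / (2 * w^2))
}

lorentz_dip <- function(f, center, fwhm) {
  hw <- fwhm / 2
  hw^2 / ((f - center)^2 + hw^2)
}

gauss_dip <- function(f, center, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(f - center)^2 / (2 * s^2))
}

#' Generate a synthetic scattered reflectivity spectrum
#'
#' Builds the deterministic profile
#' \deqn{|\rho(f)|^2 = |r|^2 \cdot \mathrm{Rayleigh}(f) \cdot \mathrm{Lobe}(f)
#'   \cdot \prod_l (1 - d_l L_l(f)) \cdot \prod_v (1 - d_v G_v(f))}
#' (Rayleigh roll-off, off-specular collection lobe, Lorentzian resonance
#' dips, Gaussian water-vapour dips), then applies seeded measurement noise:
#' multiplicative relative noise of standard deviation `10^(-snr_db/10)` plus
#' additive noise-floor noise, clipped below at the noise floor.  The same
#' scenario and seed always produce bit-identical spectra.
#'
#' @param scenario A `thz_scenario`.
#' @param line_shape Resonance dip profile, `"lorentzian"` (default) or
#'   `"gaussian"`.
#' @return A `thz_spectrum` of kind `"reflectivity"`.
#' @examples
#' s <- thz_simulate(thz_preset("paba", 220, seed = 7))
#' @export
thz_simulate <- function(scenario, line_shape = c("lorentzian", "gaussian")) {
  line_shape <- match.arg(line_shape)
  sc <- scenario
  f <- seq(sc$band[1], sc$band[2], by = sc$delta_f)
  if (abs((f[length(f)] - sc$band[2])) > sc$delta_f / 2)
    stop_thz("Band is not commensurate with the frequency step.", "thz_invalid_band")
  p <- sc$r2 * rayleigh_factor(f, sc$sigma_um, sc$theta_deg)
  p <- p * angular_lobe(f, sc$sigma_um, sc$offset_deg)
  dip <- if (line_shape == "lorentzian") lorentz_dip else gauss_dip
  for (i in seq_len(nrow(sc$lines)))
    p <- p * (1 - sc$lines$depth[i] * dip(f, sc$lines$center[i], sc$lines$fwhm[i]))
  if (sc$water_vapor)
    for (i in seq_len(nrow(water_lines)))
      p <- p * (1 - water_lines$depth[i] *
                  gauss_dip(f, water_lines$center[i], water_lines$fwhm[i]))
  if (is.finite(sc$snr_db)) {
    p <- local_seed(sc$seed, {
      p * (1 + rnorm(length(f), 0, 10^(-sc$snr_db / 10))) +
        sc$noise_floor * rnorm(length(f))
    })
  }
  thz_spectrum(f, pmax(p, sc$noise_floor), kind = "reflectivity", band = sc$band)
}

#' Preset measurement scenarios
#'
#' Scenarios emulating the study's sample disks: alpha-lactose monohydrate or
#' PABA pressed against sandpaper of grit 220, 120, 80 or 40, measured at a
#' 35-degree incidence angle in the specular direction or at an off-specular
#' detection offset.  The RMS surface height comes from the per-material
#' column of [sandpaper_roughness].
#'
#' @param material `"lactose"` or `"paba"`.
#' @param grit Sandpaper grit: 220, 120, 80 or 40.
#' @param offset_deg Detection offset from specular, degrees.
#' @param seed Scenario seed.
#' @param ... Overrides passed on to [thz_scenario()].
#' @return A `thz_scenario`.
#' @examples
#' thz_preset("paba", 220)$sigma_um    # 15
#' @export
thz_preset <- function(material = c("lactose", "paba"),
                       grit = c(220, 120, 80, 40),
                       offset_deg = 0, seed = 1L, ...) {
  material <- match.arg(material)
  grit <- as.integer(grit)[1]
  row <- which(sandpaper_roughness$grit == grit)
  if (!length(row))
    stop_thz(sprintf("Unknown grit %s; presets exist for %s.",
                     format(grit),
                     paste(sandpaper_roughness$grit, collapse = ", ")),
             "thz_unknown_preset")
  sigma <- if (material == "lactose") sandpaper_roughness$sigma_lactose_um[row]
           else sandpaper_roughness$sigma_paba_um[row]
  lines <- if (material == "lactose") lactose_lines else paba_lines
  args <- modifyList(list(lines = lines, sigma_um = sigma, theta_deg = 35,
                          offset_deg = offset_deg, seed = seed),
                     list(...))
  do.call(thz_scenario, args)
}

#' Draw a random absorption line list
#'
#' Samples `n` line centres uniformly over `center_range` with a minimum
#' mutual separation (rejection sampling), and uniform depths and widths.
#' Used to exercise the identification pipeline on randomised fingerprints.
#'
#' @param n Number of lines.
#' @param center_range Range for the centres, THz.
#' @param min_sep Minimum separation between centres, THz.
#' @param depth_range,fwhm_range Ranges for depths and widths.
#' @param seed Integer seed.
#' @return A line-list tibble (`center`, `depth`, `fwhm`).
#' @export
random_lines <- function(n = 3, center_range = c(0.4, 1.5), min_sep = 0.15,
                         depth_range = c(0.3, 0.8), fwhm_range = c(0.025, 0.040),
                         seed = 1L) {
  local_seed(seed, {
    repeat {
      cen <- sort(runif(n, center_range[1], center_range[2]))
      if (n < 2L || min(diff(cen)) >= min_sep) break
    }
    tibble(center = cen,
           depth = runif(n, depth_range[1], depth_range[2]),
           fwhm = runif(n, fwhm_range[1], fwhm_range[2]))
  })
}
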