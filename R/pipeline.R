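#' Shrinkage pipeline configuration
#'
#' Collects the tunable parameters of the identification pipeline.  Defaults
#' are the study values: LA(8) filters, J = 6 decomposition levels, level
#' exclusion outside 0.2%-25% of total second-order total variation, 200-GHz
#' threshold windows centred at 0.3 and 1.7 THz, and a 5% prominence floor
#' for peak calling.
#'
#' @param wavelet_length LA filter length L.
#' @param depth Decomposition depth J.
#' @param tv_upper,tv_lower Inclusive level-selection bounds on the
#'   second-order total-variation fraction.
#' @param windows List of `(center, width)` threshold windows, THz.
#' @param band Optional analysis band override, THz.
#' @param prominence_floor Peak-calling prominence floor (fraction of the
#'   derivative's dynamic range).
#' @param match_tol Peak-to-line matching tolerance, THz.
#' @param refine_peaks Refine peak positions to the adjacent zero crossing.
#' @return A `thz_config` list.
#' @export
shrinkage_config <- function(wavelet_length = 8, depth = 6,
                             tv_upper = 0.25, tv_lower = 0.002,
                             windows = list(c(0.3, 0.2), c(1.7, 0.2)),
                             band = NULL, prominence_floor = 0.05,
                             match_tol = 0.02, refine_peaks = TRUE) {
  structure(list(wavelet_length = wavelet_length, depth = depth,
                 tv_upper = tv_upper, tv_lower = tv_lower, windows = windows,
                 band = band, prominence_floor = prominence_floor,
                 match_tol = match_tol, refine_peaks = refine_peaks),
            class = "thz_config")
}

#' Identify resonant fingerprints by wavelet shrinkage
#'
#' Runs the full retrieval pipeline on a scattered reflectivity spectrum:
#' negative derivative, forward MODWT, zero-phase alignment, level selection
#' by second-order total variation, interval-based threshold selection, hard
#' thresholding with level zeroing, reversal of the alignment, inverse MODWT
#' and resonance peak extraction.
#'
#' @param x A `thz_spectrum` of kind `"reflectivity"`, or a `thz_scenario`
#'   (which is simulated first).
#' @param config A [shrinkage_config()].
#' @param lines Optional reference line list for peak matching (a scenario
#'   input supplies its own).
#' @return A `thz_identification` object with components `peaks`
#'   (a `thz_peaks` tibble), `levels`, `thresholds`, `derivative`,
#'   `reconstructed`, `input` and `config`.  [tidy()] returns the peak
#'   table; [glance()] a one-row summary.
#' @examples
#' res <- thz_identify(thz_preset("paba", 220, seed = 7))
#' res$peaks
#' @export
thz_identify <- function(x, config = shrinkage_config(), lines = NULL) {
  if (inherits(x, "thz_scenario")) {
    if (is.null(lines) && nrow(x$lines)) lines <- x$lines
    x <- thz_simulate(x)
  }
  if (!inherits(x, "thz_spectrum"))
    stop_thz("`thz_identify()` needs a thz_spectrum or thz_scenario.",
             "thz_invalid_input")
  if (!is.null(config$band)) x <- crop_band(x, config$band)
  deriv <- stage(negative_derivative(x), "negative_derivative")
  dec <- stage(modwt(deriv, la_filters(config$wavelet_length), config$depth),
               "modwt")
  dec <- stage(modwt_align(dec), "modwt_align")
  profile <- stage(tv2_levels(dec), "tv2_levels")
  profile <- stage(select_levels(profile, config$tv_upper, config$tv_lower),
                   "select_levels")
  keep <- kept_levels(profile)
  thresholds <- stage(compute_thresholds(dec, keep, config$windows),
                      "compute_thresholds")
  excluded <- setdiff(seq_len(dec$J), keep)
  shrunk <- stage(hard_threshold(dec, thresholds, excluded), "hard_threshold")
  rec <- stage(reconstruct(shrunk), "reconstruct")
  spans <- threshold_windows(thresholds)
  exclude <- purrr::map(spans[lengths(purrr::map(spans, "idx")) > 0],
                        ~ c(.x$lo, .x$hi))
  peaks <- stage(find_resonances(rec, config$prominence_floor,
                                 reference = deriv, exclude = exclude,
                                 lines = lines, match_tol = config$match_tol,
                                 refine = config$refine_peaks),
                 "find_resonances")
  structure(list(peaks = peaks, levels = profile, thresholds = thresholds,
                 derivative = deriv, reconstructed = rec, input = x,
                 config = config),
            class = "thz_identification")
}

# annotate stage failures with the stage name
stage <- function(value, name) {
  withCallingHandlers(
    tryCatch(value,
             error = function(e) {
               stop_thz(sprintf("Stage `%s` failed: %s", name, conditionMessage(e)),
                        "thz_stage_error")
             }),
    warning = function(w) {
      warn(sprintf("[%s] %s", name, conditionMessage(w)))
      rlang::cnd_muffle(w)
    })
}

#' @export
print.thz_identification <- function(x, ...) {
  cat("Wavelet-shrinkage identification\n")
  cat(sprintf("  kept levels : %s\n",
              paste(kept_levels(x$levels), collapse = ", ")))
  cat(sprintf("  thresholds  : %s\n",
              paste(sprintf("%.3g", x$thresholds$tau), collapse = ", ")))
  cat(sprintf("  peaks (%d)  : %s THz\n", nrow(x$peaks),
              paste(sprintf("%.3f", x$peaks$frequency), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.thz_identification <- function(x, ...) {
  out <- as_tibble(x$peaks)
  class(out) <- setdiff(class(out), "thz_peaks")
  out
}

#' @export
glance.thz_identification <- function(x, ...) {
  tibble(n_peaks = nrow(x$peaks),
         n_levels_kept = length(kept_levels(x$levels)),
         max_tau = max(x$thresholds$tau),
         dominant_frequency = if (nrow(x$peaks))
           x$peaks$frequency[which.max(x$peaks$amplitude)] else NA_real_,
         highest_frequency = if (nrow(x$peaks))
           max(x$peaks$frequency) else NA_real_)
}

#' Estimate surface roughness from a reflectivity spectrum
#'
#' Convenience wrapper: fits the Kirchhoff roll-off with [fit_sigma()] and
#' evaluates the Fraunhofer criterion for the fitted RMS height.
#'
#' @inheritParams fit_sigma
#' @return A `thz_kirchhoff_fit` with an additional `fraunhofer` element
#'   (tibble with `lambda_um` and `freq_ghz`).
#' @export
thz_roughness <- function(s, theta_deg = 35, fit_band = NULL, rel_floor = 0.01) {
  fit <- fit_sigma(s, theta_deg, fit_band, rel_floor)
  fit$fraunhofer <- if (fit$sigma_um > 0) fraunhofer_threshold(fit$sigma_um, theta_deg)
                    else tibble(lambda_um = 0, freq_ghz = Inf)
  fit
}
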