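resolve_windows <- function(freq, band, windows) {
  spans <- purrr::map(windows, function(w) {
    lo <- max(w[1] - w[2] / 2, band[1])
    hi <- min(w[1] + w[2] / 2, band[2])
    clipped <- lo > w[1] - w[2] / 2 + 1e-12 || hi < w[1] + w[2] / 2 - 1e-12
    empty <- hi - lo <= 1e-12
    idx <- if (empty) integer(0) else which(freq >= lo - 1e-12 & freq <= hi + 1e-12)
    list(center = w[1], width = w[2], lo = lo, hi = hi,
         clipped = clipped, idx = idx)
  })
  if (all(lengths(purrr::map(spans, "idx")) == 0L))
    stop_thz("All threshold windows fall outside the analysis band.",
             "thz_empty_windows")
  for (sp in spans)
    if (sp$clipped)
      warn(sprintf("Threshold window at %.3g THz clipped to [%.3g, %.3g] THz by the band.",
                   sp$center, sp$lo, sp$hi))
  spans
}

#' Interval-based shrinkage thresholds
#'
#' For each kept decomposition level, the threshold \eqn{\tau_j} is the
#' amplitude of the largest aligned wavelet coefficient inside the
#' noise-and-scattering intervals: by default a 200-GHz window centred at
#' 300 GHz and a 200-GHz window centred at 1.7 THz.  Those intervals contain
#' the low-frequency scattering artifacts, the high-frequency noise floor and
#' the strong atmospheric water-vapour cluster, so their largest coefficient
#' bounds the artifact amplitude at each scale.  Zero-phase alignment is
#' required so the windows address the right coefficients.
#'
#' @param d An aligned `thz_modwt` with a frequency axis.
#' @param levels Integer vector of kept levels (e.g. from [select_levels()]).
#' @param windows List of `(center, width)` pairs in THz.
#' @param band Analysis band; defaults to the decomposition's band.  Windows
#'   are clipped to the band (with a warning); it is an error for every window
#'   to be empty.
#' @return A `thz_thresholds` tibble (`level`, `tau`) with the resolved
#'   windows as attribute.
#' @export
compute_thresholds <- function(d, levels,
                               windows = list(c(0.3, 0.2), c(1.7, 0.2)),
                               band = NULL) {
  if (!is_aligned(d))
    stop_thz("Threshold selection needs aligned coefficients; call `modwt_align()`.",
             "thz_alignment_error")
  band <- band %||% d$band %||% range(d$frequency)
  spans <- resolve_windows(d$frequency, band, windows)
  idx <- sort(unique(unlist(purrr::map(spans, "idx"))))
  tau <- vapply(levels, function(j) max(abs(d$W[idx, j])), numeric(1))
  new_tibble(list(level = as.integer(levels), tau = unname(tau)),
             nrow = length(levels), class = "thz_thresholds",
             windows = spans)
}

threshold_windows <- function(thresholds) attr(thresholds, "windows")

#' Hard-threshold wavelet coefficients and zero excluded levels
#'
#' Applies level-wise hard thresholding to the aligned coefficients: at each
#' kept level, coefficients with \eqn{|\tilde W_j(f)| < \tau_j} are set to
#' zero and the rest are kept verbatim; every wavelet coefficient of an
#' excluded level is zeroed.  Scaling coefficients are untouched.  The
#' operation is idempotent for a fixed threshold set.
#'
#' @param d An aligned `thz_modwt`.
#' @param thresholds A `thz_thresholds` tibble (or anything with `level` and
#'   `tau` columns).
#' @param excluded Integer vector of levels whose wavelet coefficients are
#'   zeroed entirely.
#' @return The modified (still aligned) `thz_modwt`.
#' @export
hard_threshold <- function(d, thresholds, excluded = integer(0)) {
  if (!is_aligned(d))
    stop_thz("Hard thresholding operates on aligned coefficients.",
             "thz_alignment_error")
  for (i in seq_len(nrow(thresholds))) {
    j <- thresholds$level[i]
    w <- d$W[, j]
    w[abs(w) < thresholds$tau[i]] <- 0
    d$W[, j] <- w
  }
  for (j in excluded) d$W[, j] <- 0
  d
}

#' Reconstruct the shrunk derivative spectrum
#'
#' Reverses the zero-phase circular advancement and runs the inverse MODWT
#' pyramid, yielding the reconstructed negative-derivative spectrum on the
#' original frequency axis.
#'
#' @param d An aligned (possibly thresholded) `thz_modwt`.
#' @return A `thz_spectrum` of kind `"derivative"`.
#' @export
reconstruct <- function(d) {
  if (!is_aligned(d))
    stop_thz("`reconstruct()` expects an aligned decomposition.",
             "thz_alignment_error")
  imodwt(modwt_unalign(d))
}

# scipy-style prominence: drop from the peak to the higher of the two valley
# floors between the peak and the nearest higher ground on each side
peak_prominences <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(i) {
    h <- x[i]
    lmin <- h
    l <- i - 1L
    while (l >= 1L) {
      lmin <- min(lmin, x[l])
      if (x[l] > h) break
      l <- l - 1L
    }
    rmin <- h
    r <- i + 1L
    while (r <= n) {
      rmin <- min(rmin, x[r])
      if (x[r] > h) break
      r <- r + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Locate resonance peaks in a derivative spectrum
#'
#' Finds strict local maxima with positive amplitude whose prominence reaches
#' `prominence_floor` times the dynamic range of the reference signal.  The
#' reference defaults to the spectrum itself; the identification pipeline
#' passes the pre-shrinkage derivative so that a nearly empty reconstruction
#' cannot promote numerical wiggles to peaks.  The dynamic range is measured
#' on a 3-point running median of the reference, which ignores one- or
#' two-bin spikes (such as unresolved water-vapour lines).
#'
#' For a symmetric absorption dip the negative derivative peaks on the
#' low-frequency flank and crosses zero at the dip centre, so when
#' `refine = TRUE` the reported frequency is the linearly interpolated zero
#' crossing within fifteen bins above the maximum (falling back to the
#' maximum's position when the signal does not cross zero there).
#'
#' Two suppression rules clean up artifacts of the hard-threshold
#' reconstruction, both applied to the refined positions, keeping the
#' larger-amplitude peak: peaks closer than `min_sep` are merged (a clipped
#' line's post-trough rebound sits within a few bins of its parent), and a
#' peak below `sidelobe_ratio` times a larger peak within `sidelobe_radius`
#' is treated as that feature's wavelet sidelobe (the coarsest kept LA(8)
#' scale places sidelobes up to ~0.15 THz away at up to about half the main
#' lobe).
#'
#' @param s A `thz_spectrum` of kind `"derivative"` (or any spectrum).
#' @param prominence_floor Fraction of the reference dynamic range a peak's
#'   prominence must reach (default 5%).
#' @param reference Optional `thz_spectrum` or numeric vector whose dynamic
#'   range scales the prominence floor.
#' @param exclude List of `(lo, hi)` frequency intervals (THz) whose local
#'   maxima are not reported (the pipeline passes the threshold windows:
#'   anything peaking inside a declared noise/scattering interval is an
#'   artifact by construction).
#' @param lines Optional reference line list (tibble with a `center` column,
#'   or numeric vector) to match peaks against.
#' @param match_tol Matching tolerance in THz (default 0.02).
#' @param refine Refine peak positions to the adjacent zero crossing.
#' @param min_sep Minimum separation between reported peaks, THz.
#' @param sidelobe_ratio,sidelobe_radius Sidelobe suppression: drop a peak
#'   whose amplitude is below `sidelobe_ratio` times that of a larger peak
#'   within `sidelobe_radius` THz.  Set `sidelobe_ratio = 0` to disable.
#' @return A `thz_peaks` tibble: `frequency`, `amplitude`, `prominence`, and
#'   when `lines` is given `line_center` and `deviation` for matched peaks.
#' @export
find_resonances <- function(s, prominence_floor = 0.05, reference = NULL,
                            exclude = NULL, lines = NULL, match_tol = 0.02,
                            refine = TRUE, min_sep = 0.05,
                            sidelobe_ratio = 0.5, sidelobe_radius = 0.16) {
  x <- s$value
  freq <- s$frequency
  n <- length(x)
  ref <- if (is.null(reference)) x
         else if (inherits(reference, "data.frame")) reference$value
         else as.numeric(reference)
  ref <- runmed(ref, 3)
  floor_abs <- prominence_floor * (max(ref) - min(ref))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  cand <- cand[x[cand] > 0]
  if (length(cand)) {
    prom <- peak_prominences(x, cand)
    keep <- prom >= floor_abs & floor_abs > 0
    cand <- cand[keep]; prom <- prom[keep]
  } else prom <- numeric(0)
  if (!is.null(exclude) && length(cand)) {
    inside <- rep(FALSE, length(cand))
    for (w in exclude)
      inside <- inside | (freq[cand] >= w[1] - 1e-12 & freq[cand] <= w[2] + 1e-12)
    cand <- cand[!inside]; prom <- prom[!inside]
  }
  pos <- freq[cand]
  if (refine && length(cand)) {
    for (ii in seq_along(cand)) {
      i <- cand[ii]
      for (j in i:min(i + 15L, n - 1L)) {
        if (x[j] >= 0 && x[j + 1] < 0) {
          pos[ii] <- freq[j] + (freq[j + 1] - freq[j]) * x[j] / (x[j] - x[j + 1])
          break
        }
      }
    }
  }
  # merge/sidelobe suppression, strongest peaks first
  if (length(cand) > 1L) {
    amp <- x[cand]
    keep_idx <- integer(0)
    for (i in order(amp, decreasing = TRUE)) {
      ok <- TRUE
      for (k in keep_idx) {
        dfk <- abs(pos[i] - pos[k])
        if (dfk < min_sep - 1e-9 ||
            (dfk < sidelobe_radius - 1e-9 && amp[i] < sidelobe_ratio * amp[k])) {
          ok <- FALSE
          break
        }
      }
      if (ok) keep_idx <- c(keep_idx, i)
    }
    keep_idx <- sort(keep_idx)
    cand <- cand[keep_idx]; prom <- prom[keep_idx]; pos <- pos[keep_idx]
  }
  ord <- order(pos)
  out <- new_tibble(list(frequency = pos[ord],
                         amplitude = x[cand][ord],
                         prominence = prom[ord]),
                    nrow = length(cand), class = "thz_peaks",
                    settings = list(prominence_floor = prominence_floor,
                                    match_tol = match_tol, refine = refine,
                                    min_sep = min_sep,
                                    sidelobe_ratio = sidelobe_ratio,
                                    sidelobe_radius = sidelobe_radius))
  if (!is.null(lines)) {
    centers <- if (inherits(lines, "data.frame")) lines$center else as.numeric(lines)
    out$line_center <- NA_real_
    out$deviation <- NA_real_
    if (nrow(out)) {
      near <- vapply(out$frequency, function(p) centers[which.min(abs(centers - p))],
                     numeric(1))
      dev <- out$frequency - near
      hit <- abs(dev) <= match_tol
      out$line_center[hit] <- near[hit]
      out$deviation[hit] <- dev[hit]
    }
    attr(out, "unmatched_lines") <-
      centers[vapply(centers, function(c0)
        !nrow(out) || min(abs(out$frequency - c0)) > match_tol, logical(1))]
  }
  out
}
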