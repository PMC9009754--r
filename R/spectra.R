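#' Construct a terahertz spectrum
#'
#' A `thz_spectrum` is a tibble with a uniformly spaced `frequency` column
#' (THz) and a `value` column, tagged with the kind of quantity it stores and
#' the analysis band used by downstream processing.
#'
#' @param frequency Numeric vector of frequencies in THz, strictly increasing
#'   with uniform spacing.
#' @param value Numeric vector, same length as `frequency`.  For
#'   `kind = "reflectivity"` this is the power reflectivity \eqn{|\rho(f)|^2}
#'   and must be non-negative.
#' @param kind One of `"reflectivity"`, `"derivative"` (the negative frequency
#'   derivative of power reflectivity) or `"extinction"`.
#' @param band Length-2 numeric, the analysis band `(f1, f2)` in THz.  Defaults
#'   to the full frequency range.
#' @return A `thz_spectrum` tibble with columns `frequency` and `value`.
#' @examples
#' f <- seq(0.2, 1.8, by = 0.005)
#' s <- thz_spectrum(f, 0.3 * exp(-f^2), kind = "reflectivity")
#' delta_f(s)
#' @export
thz_spectrum <- function(frequency, value,
                         kind = c("reflectivity", "derivative", "extinction"),
                         band = NULL) {
  kind <- match.arg(kind)
  frequency <- as.numeric(frequency)
  value <- as.numeric(value)
  if (length(frequency) != length(value))
    stop_thz("`frequency` and `value` must have the same length.", "thz_invalid_spectrum")
  n <- length(frequency)
  if (n < 16L)
    stop_thz(sprintf("A spectrum needs at least 16 points, got %d.", n),
             "thz_invalid_spectrum")
  if (anyNA(frequency) || anyNA(value))
    stop_thz("Spectrum axis and values must be finite.", "thz_invalid_spectrum")
  if (any(diff(frequency) <= 0))
    stop_thz("`frequency` must be strictly increasing (duplicated or unsorted values found).",
             "thz_invalid_spectrum")
  if (!is_uniform(frequency))
    stop_thz("`frequency` must be uniformly spaced.", "thz_invalid_spectrum")
  if (kind == "reflectivity" && any(value < 0))
    stop_thz("Reflectivity values must be non-negative.", "thz_invalid_spectrum")
  if (is.null(band)) band <- range(frequency)
  band <- as.numeric(band)
  if (length(band) != 2L || band[1] >= band[2] ||
      band[1] < frequency[1] - 1e-12 || band[2] > frequency[n] + 1e-12)
    stop_thz("`band` must be (f1, f2) with f1 < f2, inside the frequency axis.",
             "thz_invalid_spectrum")
  new_tibble(list(frequency = frequency, value = value),
             nrow = n, class = "thz_spectrum",
             kind = kind, band = band)
}

#' @export
#' @rdname thz_spectrum
#' @param s A `thz_spectrum`.
delta_f <- function(s) {
  f <- s$frequency
  (f[length(f)] - f[1]) / (length(f) - 1L)
}

spectrum_kind <- function(s) attr(s, "kind") %||% "reflectivity"
spectrum_band <- function(s) attr(s, "band") %||% range(s$frequency)
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.thz_spectrum <- function(x, ...) {
  cat(sprintf("<thz_spectrum: %s, %d points, %.4g-%.4g THz (df = %.4g), band %.3g-%.3g>\n",
              spectrum_kind(x), nrow(x), x$frequency[1], x$frequency[nrow(x)],
              delta_f(x), spectrum_band(x)[1], spectrum_band(x)[2]))
  NextMethod()
}

#' Crop a spectrum to its analysis band
#'
#' @param s A `thz_spectrum`.
#' @param band Optional band override, `(f1, f2)` in THz.
#' @return A `thz_spectrum` restricted to the band.
#' @export
crop_band <- function(s, band = NULL) {
  band <- band %||% spectrum_band(s)
  keep <- s$frequency >= band[1] - 1e-12 & s$frequency <= band[2] + 1e-12
  thz_spectrum(s$frequency[keep], s$value[keep], kind = spectrum_kind(s),
               band = band)
}

#' Read and write spectrum files
#'
#' Spectrum files are two-column numeric text (comma, tab or whitespace
#' separated): frequency and value.  An optional leading `#` comment block may
#' carry `kind:`, `band:` and `unit:` metadata; `write_spectrum()` emits it.
#'
#' @param path File path.
#' @param kind Spectrum kind, used when the file carries no metadata header.
#' @param unit Frequency unit of the file, `"THz"` or `"GHz"`; values are
#'   normalised to THz.
#' @param band Optional analysis band in THz.
#' @return `read_spectrum()` returns a `thz_spectrum`;
#'   `write_spectrum()` invisibly returns `path`.
#' @export
read_spectrum <- function(path, kind = "reflectivity", unit = c("THz", "GHz"),
                          band = NULL) {
  unit <- match.arg(unit)
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^\\s*#", lines, value = TRUE)
  for (m in meta) {
    if (grepl("kind:", m)) kind <- trimws(sub(".*kind:", "", m))
    if (grepl("unit:", m)) unit <- trimws(sub(".*unit:", "", m))
    if (grepl("band:", m))
      band <- as.numeric(strsplit(trimws(sub(".*band:", "", m)), "[,[:space:]]+")[[1]])
  }
  tab <- parse_two_columns(lines, path)
  f <- tab[[1]]
  if (identical(toupper(unit), "GHZ")) {
    f <- f / 1000
    if (!is.null(band)) band <- band / 1000
  }
  thz_spectrum(f, tab[[2]], kind = kind, band = band)
}

parse_two_columns <- function(lines, path) {
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    stop_thz(sprintf("No data rows in '%s'.", path), "thz_io_error")
  # drop a single non-numeric header row if present
  first <- strsplit(trimws(lines[1]), "[,\t ]+")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) lines <- lines[-1]
  parts <- strsplit(trimws(lines), "[,\t ]+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop_thz(sprintf("Row %d of '%s' does not have two columns.", bad[1], path),
             "thz_io_error")
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(x) || anyNA(y))
    stop_thz(sprintf("Non-numeric entries in '%s'.", path), "thz_io_error")
  list(x, y)
}

#' @rdname read_spectrum
#' @param s A `thz_spectrum` to write.
#' @param digits Significant digits written.
#' @export
write_spectrum <- function(s, path, digits = 15) {
  hdr <- c(sprintf("# kind: %s", spectrum_kind(s)),
           sprintf("# band: %.10g %.10g", spectrum_band(s)[1], spectrum_band(s)[2]),
           "# unit: THz",
           "# frequency,value")
  rows <- sprintf("%.*g,%.*g", digits, s$frequency, digits, s$value)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a time-domain pulse trace
#'
#' Pulse-trace files are two-column numeric text: time (ps) and field
#' amplitude (arbitrary units), uniformly sampled.
#'
#' @param path File path.
#' @return A `thz_pulse` tibble with columns `time` (ps) and `field`.
#' @export
read_pulse_trace <- function(path) {
  tab <- parse_two_columns(readLines(path, warn = FALSE), path)
  thz_pulse(tab[[1]], tab[[2]])
}

#' @rdname read_pulse_trace
#' @param time Time axis in ps, uniformly spaced.
#' @param field Field amplitude, same length as `time`.
#' @export
thz_pulse <- function(time, field) {
  time <- as.numeric(time); field <- as.numeric(field)
  if (length(time) != length(field))
    stop_thz("`time` and `field` must have the same length.", "thz_invalid_trace")
  if (!is_uniform(time))
    stop_thz("`time` must be uniformly spaced.", "thz_invalid_trace")
  new_tibble(list(time = time, field = field), nrow = length(time),
             class = "thz_pulse")
}

#' Power reflectivity from sample and reference pulse traces
#'
#' Computes \eqn{|\rho(f)|^2 = |F\{sample\}|^2 / |F\{reference\}|^2} on the
#' discrete frequency grid implied by the common time axis, restricted to the
#' requested band.  A perfect reflector is the usual reference.
#'
#' @param sample,reference `thz_pulse` traces with equal time steps.
#' @param band Analysis band `(f1, f2)` in THz.
#' @param window Taper applied to both traces before transforming:
#'   `"none"` or `"hann"`.
#' @param pad Zero-padding factor (integer >= 1); the transform length is
#'   `pad * n`.
#' @param floor Relative magnitude floor for the reference: frequencies where
#'   `|F{reference}|` falls below `floor * max|F{reference}|` inside the band
#'   are an error.
#' @return A `thz_spectrum` of kind `"reflectivity"`.
#' @export
reflectivity_from_traces <- function(sample, reference, band = c(0.2, 1.8),
                                     window = c("none", "hann"), pad = 1L,
                                     floor = 1e-6) {
  window <- match.arg(window)
  if (nrow(sample) != nrow(reference))
    stop_thz("Sample and reference traces must have the same length.",
             "thz_invalid_trace")
  dt_s <- sample$time[2] - sample$time[1]
  dt_r <- reference$time[2] - reference$time[1]
  if (abs(dt_s - dt_r) > 1e-9 * dt_s)
    stop_thz("Sample and reference traces must share the time step.",
             "thz_invalid_trace")
  n <- nrow(sample)
  m <- as.integer(pad) * n
  w <- switch(window,
              none = rep(1, n),
              hann = 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)))
  fs <- stats::fft(c(sample$field * w, numeric(m - n)))
  fr <- stats::fft(c(reference$field * w, numeric(m - n)))
  freq <- (seq_len(m) - 1L) / (m * dt_s)   # THz, since time is in ps
  keep <- freq >= band[1] - 1e-12 & freq <= band[2] + 1e-12
  band <- c(max(band[1], min(freq[keep])), min(band[2], max(freq[keep])))
  mag_r <- Mod(fr[keep])
  low <- mag_r < floor * max(mag_r)
  if (any(low))
    stop_thz(sprintf(
      "Reference spectral magnitude below floor inside the band, first at %.4g THz.",
      freq[keep][which(low)[1]]), "thz_reference_floor")
  thz_spectrum(freq[keep], (Mod(fs[keep]) / mag_r)^2,
               kind = "reflectivity", band = band)
}

#' Negative derivative of power reflectivity
#'
#' Seeds the wavelet pyramid: \eqn{\tilde V_0(f) = -\,d|\rho(f)|^2/df},
#' estimated by central differences in the interior and one-sided differences
#' at the end points.
#'
#' @param s A `thz_spectrum` of kind `"reflectivity"`.
#' @return A `thz_spectrum` of kind `"derivative"` on the same axis and band.
#' @export
negative_derivative <- function(s) {
  if (!identical(spectrum_kind(s), "reflectivity"))
    stop_thz("`negative_derivative()` expects a reflectivity spectrum.",
             "thz_invalid_kind")
  x <- s$value
  n <- length(x)
  df <- delta_f(s)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * df)
  d[1] <- (x[2] - x[1]) / df
  d[n] <- (x[n] - x[n - 1]) / df
  thz_spectrum(s$frequency, -d, kind = "derivative", band = spectrum_band(s))
}
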