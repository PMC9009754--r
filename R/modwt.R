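# Circular filtering with upsampled taps:
# out[t] = sum_k filt[k] * x[(t + sgn * step * k) mod N]   (0-based t, k)
circ_filter <- function(x, filt, step, sgn = -1L) {
  n <- length(x)
  out <- numeric(n)
  idx <- seq_len(n) - 1L
  for (k in seq_along(filt) - 1L)
    out <- out + filt[k + 1L] * x[((idx + sgn * step * k) %% n) + 1L]
  out
}

#' Forward MODWT pyramid
#'
#' Maximal overlap discrete wavelet transform of the derivative spectrum (or
#' any uniformly sampled sequence) by the recursive pyramid algorithm with
#' circular boundary treatment:
#' \deqn{\tilde W_j(t) = \sum_k \tilde h(k)\, \tilde V_{j-1}(t - 2^{j-1}k \bmod N)}
#' and likewise for \eqn{\tilde V_j} with the scaling filter, starting from
#' \eqn{\tilde V_0 = x}.  The transform is undecimated: every level keeps all
#' N coefficients, which makes it shift-equivariant and energy preserving.
#'
#' @param x A `thz_spectrum` (typically of kind `"derivative"`) or a numeric
#'   vector.
#' @param filters A `thz_filter_pair` from [la_filters()].
#' @param J Decomposition depth; must satisfy `J <= floor(log2(N))`.
#' @return A `thz_modwt` object: wavelet coefficient matrix `W` (N x J),
#'   scaling coefficients `V` (level J), filters, per-level advance state and
#'   the originating frequency axis (if any).
#' @examples
#' d <- modwt(sin(seq_len(64) / 5), la_filters(8), J = 4)
#' x <- imodwt(d)
#' @export
modwt <- function(x, filters = la_filters(8), J = 6) {
  if (inherits(x, "thz_spectrum")) {
    freq <- x$frequency
    band <- spectrum_band(x)
    v <- x$value
  } else {
    freq <- NULL
    band <- NULL
    v <- as.numeric(x)
  }
  n <- length(v)
  if (!all(is.finite(v)))
    stop_thz("Input to `modwt()` must be finite.", "thz_invalid_input")
  J <- as.integer(J)
  if (J < 1L || J > floor(log2(n)))
    stop_thz(sprintf("J = %d too deep for N = %d (max %d).", J, n, floor(log2(n))),
             "thz_invalid_depth")
  W <- matrix(0, n, J)
  for (j in seq_len(J)) {
    step <- 2L^(j - 1L)
    W[, j] <- circ_filter(v, filters$h, step, -1L)
    v <- circ_filter(v, filters$g, step, -1L)
  }
  colnames(W) <- paste0("level", seq_len(J))
  structure(list(W = W, V = v, J = J, filters = filters,
                 advances = integer(J), frequency = freq, band = band),
            class = "thz_modwt")
}

#' @export
print.thz_modwt <- function(x, ...) {
  cat(sprintf("<thz_modwt: N = %d, J = %d, %s, %s>\n",
              nrow(x$W), x$J, x$filters$family,
              if (is_aligned(x)) "aligned (zero-phase)" else "raw alignment"))
  invisible(x)
}

# the advance that brings level-j wavelet coefficients to zero phase,
# as printed for the LA family: 2^(j-1) (L-1) - nu
phase_advance <- function(filters, j) {
  as.integer(2^(j - 1) * (filters$L - 1) - filters$nu)
}

is_aligned <- function(d) all(d$advances != 0L)

circ_shift <- function(x, by) {
  n <- length(x)
  x[((seq_len(n) - 1L + by) %% n) + 1L]
}

#' Zero-phase alignment of MODWT wavelet coefficients
#'
#' Circularly advances the level-j wavelet coefficients by
#' \eqn{2^{j-1}(L-1)-\nu} so that wavelet-domain features line up with the
#' input signal (for LA(8): 10, 17, 31, 59, 115 samples at levels 1-5).
#' Scaling coefficients are never advanced.  `modwt_unalign()` reverses the
#' advancement exactly; the inverse transform requires raw alignment.
#'
#' @param d A `thz_modwt` object.
#' @return The object with advanced (or restored) coefficients.
#' @export
modwt_align <- function(d) {
  if (is_aligned(d))
    stop_thz("Decomposition is already aligned; refusing to advance twice.",
             "thz_alignment_error")
  for (j in seq_len(d$J)) {
    v <- phase_advance(d$filters, j)
    d$W[, j] <- circ_shift(d$W[, j], v)
    d$advances[j] <- v
  }
  d
}

#' @rdname modwt_align
#' @export
modwt_unalign <- function(d) {
  if (!is_aligned(d))
    stop_thz("Decomposition is not aligned; nothing to reverse.",
             "thz_alignment_error")
  for (j in seq_len(d$J)) {
    d$W[, j] <- circ_shift(d$W[, j], -d$advances[j])
    d$advances[j] <- 0L
  }
  d
}

#' Inverse MODWT pyramid
#'
#' Reconstructs the level-0 sequence by the recursive inverse pyramid
#' \deqn{\tilde V_{j-1}(t) = \sum_k \tilde h(k) \tilde W_j(t + 2^{j-1}k \bmod N)
#'   + \sum_k \tilde g(k) \tilde V_j(t + 2^{j-1}k \bmod N).}
#' The decomposition must be in raw alignment: any zero-phase circular
#' advancement has to be reversed first with [modwt_unalign()], because the
#' inverse uses the same filters as the forward transform.
#'
#' @param d A `thz_modwt` object with all advances zero.
#' @return A numeric vector of length N, or a `thz_spectrum` of kind
#'   `"derivative"` when the decomposition carries a frequency axis.
#' @export
imodwt <- function(d) {
  if (any(d$advances != 0L))
    stop_thz("Coefficients are phase-advanced; call `modwt_unalign()` before inverting.",
             "thz_alignment_error")
  v <- d$V
  for (j in rev(seq_len(d$J))) {
    step <- 2L^(j - 1L)
    v <- circ_filter(d$W[, j], d$filters$h, step, +1L) +
      circ_filter(v, d$filters$g, step, +1L)
  }
  if (!is.null(d$frequency))
    thz_spectrum(d$frequency, v, kind = "derivative", band = d$band)
  else v
}

#' @export
tidy.thz_modwt <- function(x, ...) {
  n <- nrow(x$W)
  lev <- rep(seq_len(x$J), each = n)
  out <- tibble(
    level = c(lev, rep(NA_integer_, n)),
    component = c(rep("wavelet", n * x$J), rep("scaling", n)),
    index = rep(seq_len(n), x$J + 1L),
    coefficient = c(as.vector(x$W), x$V))
  if (!is.null(x$frequency)) out$frequency <- rep(x$frequency, x$J + 1L)
  out
}
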