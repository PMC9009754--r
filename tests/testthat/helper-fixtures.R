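# shared fixtures, built in code at test time

grid_02_18 <- function(df = 0.005) seq(0.2, 1.8, by = df)

# a clean reflectivity with one Lorentzian dip on a flat baseline
dip_spectrum <- function(center = 1.0, depth = 0.5, fwhm = 0.03, r2 = 0.3,
                         df = 0.005) {
  f <- grid_02_18(df)
  hw <- fwhm / 2
  v <- r2 * (1 - depth * hw^2 / ((f - center)^2 + hw^2))
  thz_spectrum(f, v, kind = "reflectivity")
}

# brute-force circular MODWT convolution, written independently of the
# package internals: W[t] = sum_k h[k] x[(t - 2^(j-1) k) mod N]
brute_circ <- function(x, filt, step) {
  n <- length(x)
  out <- numeric(n)
  for (t in 0:(n - 1)) {
    acc <- 0
    for (k in seq_along(filt) - 1L)
      acc <- acc + filt[k + 1L] * x[((t - step * k) %% n) + 1L]
    out[t + 1L] <- acc
  }
  out
}

expect_peaks_match <- function(peaks, centers, tol) {
  for (c0 in centers)
    expect_lt(min(abs(peaks$frequency - c0)), tol,
              label = sprintf("distance of nearest peak to %.3f THz", c0))
}
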