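aligned_from <- function(values, df = 0.005, J = 4) {
  f <- seq(0.2, by = df, length.out = length(values))
  s <- thz_spectrum(f, values, kind = "reflectivity")
  modwt_align(modwt(negative_derivative(s), la_filters(8), J))
}

test_that("thresholds are in-window maxima and respect band clipping", {
  d <- aligned_from(rep(1, 321))        # flat: all coefficients ~0
  tau <- compute_thresholds(d, 1:4)
  expect_equal(tau$tau, rep(0, 4), tolerance = 1e-12)

  # construct a known in-window maximum at level 2
  d$W[, 2] <- 0
  d$W[30, 2] <- 0.4                     # f = 0.345 THz, inside [0.2, 0.4]
  d$W[200, 2] <- 0.9                    # f = 1.195 THz, outside both windows
  tau <- compute_thresholds(d, 2)
  expect_equal(tau$tau, 0.4, tolerance = 1e-12)

  # band ending at 1.6 THz clips the upper window to nothing
  expect_warning(
    tau2 <- compute_thresholds(d, 2, band = c(0.2, 1.6)),
    "clipped")
  expect_equal(tau2$tau, 0.4, tolerance = 1e-12)
  spans <- attr(tau2, "windows")
  expect_length(spans[[2]]$idx, 0)

  # both windows outside the band is fatal
  expect_error(compute_thresholds(d, 2, band = c(0.5, 1.5)), "outside")
})

test_that("hard thresholding follows the keep-if-at-least-tau rule", {
  d <- aligned_from(rep(1, 64), J = 3)
  d$W[, 1] <- 0
  d$W[1:3, 1] <- c(3, -1, 0.5)
  thr <- tibble::tibble(level = 1L, tau = 1)
  out <- hard_threshold(d, thr)
  expect_equal(out$W[1:3, 1], c(3, -1, 0))

  # tau = 0 is the identity
  out0 <- hard_threshold(d, tibble::tibble(level = 1L, tau = 0))
  expect_identical(out0$W, d$W)

  # idempotent
  twice <- hard_threshold(out, thr)
  expect_identical(twice$W, out$W)

  # excluded levels are zeroed wholesale, scaling coefficients untouched
  excl <- hard_threshold(d, thr, excluded = 2:3)
  expect_true(all(excl$W[, 2:3] == 0))
  expect_identical(excl$V, d$V)
})

test_that("raising a threshold never revives coefficients", {
  d <- aligned_from(abs(rnorm(128, 1, 0.2)), J = 4)
  n_surviving <- function(tau)
    sum(hard_threshold(d, tibble::tibble(level = 2L, tau = tau))$W[, 2] != 0)
  taus <- seq(0, max(abs(d$W[, 2])) * 1.1, length.out = 20)
  counts <- vapply(taus, n_surviving, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[length(counts)], 0)
})

test_that("reconstruction inverts shrinkage-free decompositions", {
  set.seed(21)
  f <- seq(0.2, 1.8, by = 0.005)
  s <- thz_spectrum(f, abs(rnorm(length(f), 1, 0.1)), kind = "reflectivity")
  deriv <- negative_derivative(s)
  d <- modwt_align(modwt(deriv, la_filters(8), 6))
  rec <- reconstruct(hard_threshold(d, tibble::tibble(level = 1:6, tau = 0)))
  expect_lt(max(abs(rec$value - deriv$value)) / max(abs(deriv$value)), 1e-10)

  # zeroing every wavelet level leaves the scaling-only baseline
  base <- reconstruct(hard_threshold(d, tibble::tibble(level = integer(0),
                                                       tau = numeric(0)),
                                     excluded = 1:6))
  ref <- d
  ref$W[] <- 0
  ref <- imodwt(modwt_unalign(ref))
  expect_equal(base$value, ref$value, tolerance = 1e-12)
})

test_that("peak calling finds maxima, honours prominence and flat inputs", {
  f <- seq(0.2, 1.8, by = 0.005)
  n <- length(f)
  # single parabolic bump
  i0 <- 150
  x <- pmax(0, 1 - ((seq_len(n) - i0) / 20)^2)
  pk <- find_resonances(thz_spectrum(f, x, kind = "derivative"), refine = FALSE)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$frequency, f[i0])

  # flat input: empty list, not an error
  flat <- find_resonances(thz_spectrum(f, numeric(n), kind = "derivative"))
  expect_equal(nrow(flat), 0L)

  # second bump below the prominence floor is dropped
  x2 <- x + 0.03 * pmax(0, 1 - ((seq_len(n) - 250) / 10)^2)
  pk2 <- find_resonances(thz_spectrum(f, x2, kind = "derivative"),
                         prominence_floor = 0.05, refine = FALSE)
  expect_equal(nrow(pk2), 1L)
  pk3 <- find_resonances(thz_spectrum(f, x2, kind = "derivative"),
                         prominence_floor = 0.02, refine = FALSE)
  expect_equal(nrow(pk3), 2L)
})

test_that("peaks match a reference line list within tolerance", {
  s <- dip_spectrum(center = 1.0, depth = 0.5, fwhm = 0.03)
  pk <- find_resonances(negative_derivative(s),
                        lines = tibble::tibble(center = c(1.0, 1.4)),
                        match_tol = 0.02)
  expect_equal(pk$line_center[1], 1.0)
  expect_lt(abs(pk$deviation[1]), 0.005)
  expect_equal(attr(pk, "unmatched_lines"), 1.4)
})

test_that("close secondary maxima are merged or treated as sidelobes", {
  f <- seq(0.2, 1.8, by = 0.005)
  n <- length(f)
  bump <- function(i0, a, w = 8) a * pmax(0, 1 - ((seq_len(n) - i0) / w)^2)
  # a 30%-amplitude satellite 0.1 THz away is suppressed as a sidelobe
  x <- bump(150, 1) + bump(170, 0.3)
  pk <- find_resonances(thz_spectrum(f, x, kind = "derivative"), refine = FALSE)
  expect_equal(nrow(pk), 1L)
  # the same satellite 0.4 THz away is a peak in its own right
  x2 <- bump(150, 1) + bump(230, 0.3)
  pk2 <- find_resonances(thz_spectrum(f, x2, kind = "derivative"), refine = FALSE)
  expect_equal(nrow(pk2), 2L)
  # suppression can be disabled
  pk3 <- find_resonances(thz_spectrum(f, x, kind = "derivative"), refine = FALSE,
                         sidelobe_ratio = 0)
  expect_equal(nrow(pk3), 2L)
})
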