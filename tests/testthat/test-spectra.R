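test_that("spectrum files parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  f <- seq(0.2, 1.8, by = 0.01)
  writeLines(c("frequency,value", sprintf("%.10f,%.10f", f, 1 - 0.3 * f)), path)
  s <- read_spectrum(path)
  expect_equal(nrow(s), 161L)
  expect_equal(delta_f(s), 0.01, tolerance = 1e-12)

  # round-trip preserves values to near machine precision
  s2path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, s2path)
  s2 <- read_spectrum(s2path)
  expect_equal(s2$value, s$value, tolerance = 1e-12)
  expect_equal(s2$frequency, s$frequency, tolerance = 1e-12)
  expect_identical(attr(s2, "kind"), "reflectivity")

  # duplicated frequency row rejected
  writeLines(c("0.2,1", "0.2,1", sprintf("%.3f,1", seq(0.21, 0.4, 0.01))), path)
  expect_error(read_spectrum(path), "increasing")

  # fewer than 16 points rejected
  writeLines(sprintf("%.2f,1", seq(0.2, 0.3, 0.01)), path)
  expect_error(read_spectrum(path), "16")

  # non-uniform axis rejected
  writeLines(sprintf("%.4f,1", c(seq(0.2, 0.3, 0.005), 0.32, seq(0.33, 0.5, 0.005))),
             path)
  expect_error(read_spectrum(path), "uniform")

  # GHz axis is normalised to THz
  writeLines(sprintf("%.1f,1", seq(200, 1800, 10)), path)
  sg <- read_spectrum(path, unit = "GHz")
  expect_equal(range(sg$frequency), c(0.2, 1.8), tolerance = 1e-12)
})

test_that("reflectivity from traces obeys identity, scaling and delay laws", {
  t <- seq(0, 102.3, by = 0.1)           # 1024 samples, 0.1 ps step
  ref <- exp(-(t - 20)^2 / 2) * cos(2 * pi * 1.0 * (t - 20))
  same <- reflectivity_from_traces(thz_pulse(t, ref), thz_pulse(t, ref))
  expect_equal(same$value, rep(1, nrow(same)), tolerance = 1e-10)

  half <- reflectivity_from_traces(thz_pulse(t, 0.5 * ref), thz_pulse(t, ref))
  expect_equal(half$value, rep(0.25, nrow(half)), tolerance = 1e-10)

  # a pure delay only changes phase, so |rho|^2 stays 1
  delayed <- c(0, ref[-length(ref)])
  del <- reflectivity_from_traces(thz_pulse(t, delayed), thz_pulse(t, ref))
  expect_equal(del$value, rep(1, nrow(del)), tolerance = 1e-8)

  # invariant to common amplitude scaling
  a <- reflectivity_from_traces(thz_pulse(t, 3 * 0.7 * ref), thz_pulse(t, 3 * ref))
  b <- reflectivity_from_traces(thz_pulse(t, 0.7 * ref), thz_pulse(t, ref))
  expect_equal(a$value, b$value, tolerance = 1e-10)

  # reference magnitude below floor is reported with the failing frequency
  expect_error(
    reflectivity_from_traces(thz_pulse(t, ref), thz_pulse(t, ref), floor = 1),
    "THz")
})

test_that("negative derivative handles linear, constant and dip profiles", {
  f <- grid_02_18()
  lin <- thz_spectrum(f, 1 - 0.1 * f, kind = "reflectivity")
  expect_equal(negative_derivative(lin)$value, rep(0.1, length(f)),
               tolerance = 1e-10)

  const <- thz_spectrum(f, rep(0.4, length(f)), kind = "reflectivity")
  expect_equal(negative_derivative(const)$value, rep(0, length(f)))

  # Gaussian dip: negative derivative is antisymmetric about the centre
  fc <- 1.0
  dip <- thz_spectrum(f, 1 - 0.5 * exp(-(f - fc)^2 / (2 * 0.02^2)),
                      kind = "reflectivity")
  d <- negative_derivative(dip)
  expect_lt(d$frequency[which.max(d$value)], fc)
  expect_gt(d$frequency[which.min(d$value)], fc)
  i_fc <- which.min(abs(d$frequency - fc))
  expect_lt(abs(d$value[i_fc]), 1e-6)
  expect_true(d$value[i_fc - 2] > 0 && d$value[i_fc + 2] < 0)

  expect_error(negative_derivative(d), "reflectivity")
})

test_that("negative derivative is linear in its input", {
  f <- grid_02_18()
  set.seed(11)
  x <- abs(rnorm(length(f))); y <- abs(rnorm(length(f)))
  sx <- thz_spectrum(f, x, kind = "reflectivity")
  sy <- thz_spectrum(f, y, kind = "reflectivity")
  sxy <- thz_spectrum(f, 2 * x + 3 * y, kind = "reflectivity")
  expect_equal(negative_derivative(sxy)$value,
               2 * negative_derivative(sx)$value + 3 * negative_derivative(sy)$value,
               tolerance = 1e-12)
})
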