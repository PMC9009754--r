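test_that("LA filter pairs satisfy the MODWT filter identities", {
  for (L in c(8, 10, 12, 14, 16, 18, 20)) {
    fp <- la_filters(L)
    expect_lt(abs(sum(fp$h)), 1e-10)
    expect_lt(abs(sum(fp$g) - 1), 1e-10)
    expect_lt(abs(sum(fp$h^2) - 0.5), 1e-10)
    expect_lt(abs(sum(fp$g^2) - 0.5), 1e-10)
    for (n in seq_len(L / 2 - 1)) {
      lag <- 2 * n
      expect_lt(abs(sum(fp$h[seq_len(L - lag)] * fp$h[(lag + 1):L])), 1e-10)
    }
  }
  expect_error(la_filters(6), "8, 10, 12, 14, 16, 18, 20")
})

test_that("LA phase parameters follow the family rule", {
  expect_identical(la_filters(8)$nu, -3)
  expect_identical(la_filters(14)$nu, -5)
  expect_identical(la_filters(10)$nu, -5)
  expect_identical(la_filters(12)$nu, -5)
  expect_identical(la_filters(16)$nu, -7)
  expect_identical(la_filters(18)$nu, -9)
  expect_identical(la_filters(20)$nu, -9)
})

test_that("constant input maps to zero wavelet and constant scaling coefficients", {
  d <- modwt(rep(3.7, 64), la_filters(8), J = 5)
  expect_lt(max(abs(d$W)), 1e-10)
  expect_equal(d$V, rep(3.7, 64), tolerance = 1e-12)
})

test_that("forward pyramid matches a brute-force circular convolution", {
  fp <- la_filters(8)
  x <- numeric(32); x[1] <- 1           # unit impulse at index 0
  d <- modwt(x, fp, J = 2)
  expect_equal(d$W[, 1], c(fp$h, numeric(32 - 8)), tolerance = 1e-14)
  # level 2 against the independent double-loop evaluation
  v1 <- brute_circ(x, fp$g, 1L)
  expect_equal(d$W[, 2], brute_circ(v1, fp$h, 2L), tolerance = 1e-14)
  expect_equal(d$V, brute_circ(v1, fp$g, 2L), tolerance = 1e-14)
})

test_that("the transform preserves energy and reconstructs perfectly", {
  set.seed(42)
  x <- rnorm(256)
  d <- modwt(x, la_filters(8), J = 6)
  e <- sum(d$W^2) + sum(d$V^2)
  expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-10)
  expect_lt(max(abs(imodwt(d) - x)) / max(abs(x)), 1e-10)

  for (L in c(14, 20)) {
    for (J in c(1, 5)) {
      set.seed(L + J)
      x <- rnorm(128)
      d <- modwt(x, la_filters(L), J = J)
      expect_lt(max(abs(imodwt(d) - x)) / max(abs(x)), 1e-10)
      e <- sum(d$W^2) + sum(d$V^2)
      expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-10)
    }
  }
})

test_that("the transform is shift equivariant", {
  set.seed(7)
  x <- rnorm(128)
  s <- 13L
  xs <- c(x[(s + 1):128], x[1:s])       # circular left shift by s
  a <- modwt(x, la_filters(8), J = 4)
  b <- modwt(xs, la_filters(8), J = 4)
  for (j in 1:4)
    expect_equal(b$W[, j], c(a$W[(s + 1):128, j], a$W[1:s, j]), tolerance = 1e-12)
  expect_equal(b$V, c(a$V[(s + 1):128], a$V[1:s]), tolerance = 1e-12)
})

test_that("zero-phase advances take the stated values and invert exactly", {
  set.seed(3)
  d <- modwt(rnorm(256), la_filters(8), J = 6)
  a <- modwt_align(d)
  expect_identical(a$advances[1:5], as.integer(c(10, 17, 31, 59, 115)))
  u <- modwt_unalign(a)
  expect_identical(u$W, d$W)            # bit-identical
  expect_identical(u$advances, integer(6))
  expect_error(modwt_align(a), "already aligned")
  expect_error(modwt_unalign(d), "not aligned")
  expect_error(imodwt(a), "unalign")
})

test_that("alignment collapses the level-dependent drift of wavelet features", {
  n <- 256; m <- 100
  x <- exp(-((seq_len(n) - m)^2) / (2 * 3^2))
  raw <- modwt(x, la_filters(8), J = 5)
  al <- modwt_align(raw)
  raw_err <- vapply(2:5, function(j) abs(which.max(abs(raw$W[, j])) - m), numeric(1))
  al_err <- vapply(2:5, function(j) abs(which.max(abs(al$W[, j])) - m), numeric(1))
  # raw misalignment grows roughly like 2^(j-1)(L-1); aligned features sit a
  # small, level-independent distance from the bump
  expect_true(all(al_err < raw_err[length(raw_err)]))
  expect_lte(max(al_err), 8)
  expect_gt(max(raw_err), 50)
  expect_lt(diff(range(al_err)), 3)
})

test_that("the inverse is linear and maps zero to zero", {
  set.seed(9)
  x <- rnorm(64)
  d <- modwt(x, la_filters(8), J = 3)
  z <- d; z$W[] <- 0; z$V[] <- 0
  expect_equal(imodwt(z), numeric(64))
  a <- d; a$W <- 2.5 * a$W; a$V <- 2.5 * a$V
  expect_equal(imodwt(a), 2.5 * x, tolerance = 1e-10)
})

test_that("depth beyond floor(log2(N)) is rejected", {
  expect_error(modwt(rnorm(32), J = 6), "too deep")
})
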