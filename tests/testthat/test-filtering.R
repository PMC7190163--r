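test_that("filter parameter invariants are enforced", {
  expect_error(filter_params(sigma_high = 1, sigma_low = 2), "larger than")
  expect_error(gaussian_high_pass(array(1, c(2, 2, 2)), sigma = 0), "positive")
  expect_error(gaussian_low_pass(array(1, c(2, 2, 2)), sigma = -1), "positive")
})

test_that("high pass removes constants and additive offsets", {
  const <- new_volume(array(0.4, c(5, 7, 7)))
  expect_lt(max(gaussian_high_pass(const, 2)), 1e-12)

  set.seed(3)
  a <- array(stats::runif(5 * 9 * 9, 0, 0.5), c(5, 9, 9))
  h1 <- gaussian_high_pass(new_volume(a), 2)
  h2 <- gaussian_high_pass(new_volume(a + 0.3), 2)
  expect_equal(unclass(h1), unclass(h2), tolerance = 1e-12)
})

test_that("separable Gaussian blur matches the dense convolution oracle", {
  set.seed(5)
  a <- array(stats::runif(11^3), c(11, 11, 11))
  sep <- fishcount:::gaussian_smooth(a, 1.3)
  oracle <- dense_gaussian_blur3(a, 1.3)
  expect_equal(sep, oracle, tolerance = 1e-10)

  hp <- gaussian_high_pass(new_volume(a), 1.3)
  expect_equal(unclass(hp), pmax(a - oracle, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("low pass reproduces the analytic kernel for a delta spike", {
  a <- array(0, c(21, 21, 21))
  a[11, 11, 11] <- 1
  sm <- gaussian_low_pass(new_volume(a), 2)
  r <- ceiling(4 * 2)
  k1 <- stats::dnorm(-r:r, sd = 2); k1 <- k1 / sum(k1)
  expect_equal(sm[11, 11, 11], k1[r + 1]^3, tolerance = 1e-12)
  expect_equal(sm[11, 11, 14], k1[r + 1]^2 * k1[r + 4], tolerance = 1e-12)
  # mass conservation for a spike far from the boundary
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # constant volumes pass through unchanged
  const <- new_volume(array(0.25, c(9, 9, 9)))
  expect_equal(unclass(gaussian_low_pass(const, 1.5)), unclass(const),
               tolerance = 1e-12)
})

test_that("bandpass suppresses smooth background below 5% of the spot peak", {
  nz <- 9; ny <- 41; nx <- 41
  grad <- outer(rep(1, ny), seq(0.1, 0.4, length.out = nx))
  a <- array(rep(grad, each = nz), c(nz, ny, nx))
  for (z in 1:nz) for (y in 1:ny) for (x in 1:nx) {
    a[z, y, x] <- a[z, y, x] +
      0.5 * exp(-((z - 5)^2 / 2 + ((y - 21)^2 + (x - 21)^2) / (2 * 1.5^2)))
  }
  f <- bandpass(new_volume(a), filter_params(sigma_high = 8, sigma_low = 1))
  peak <- max(f)
  # background corner away from the spot
  expect_lt(max(f[, 1:8, 1:8]), 0.05 * peak)
  expect_gt(peak, 0.1)

  zeros <- new_volume(array(0, c(3, 8, 8)))
  expect_true(all(bandpass(zeros) == 0))

  f2 <- bandpass(new_volume(a), filter_params(sigma_high = 8, sigma_low = 1))
  expect_identical(unclass(f), unclass(f2))
})

test_that("filtering is shift invariant and homogeneous in intensity", {
  set.seed(9)
  # signal kept far enough from the y/x borders that reflection padding sees
  # only zeros before and after the shift
  base <- array(0, c(7, 40, 40))
  base[3:5, 16:20, 16:20] <- stats::runif(75)
  p <- filter_params(sigma_high = 3, sigma_low = 1, truncate = 3)
  f0 <- bandpass(new_volume(base), p)
  shifted <- array(0, c(7, 40, 40))
  shifted[3:5, 19:23, 18:22] <- base[3:5, 16:20, 16:20]
  f1 <- bandpass(new_volume(shifted), p)
  expect_equal(f1[3:5, 19:23, 18:22], f0[3:5, 16:20, 16:20], tolerance = 1e-10)

  f3 <- bandpass(new_volume(3 * base), p)
  expect_equal(unclass(f3), 3 * unclass(f0), tolerance = 1e-10, ignore_attr = TRUE)
})
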