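test_that("SNIP leaves a flat signal untouched", {
  r <- snip_baseline(rep(7, 200), iterations = 40)
  expect_lt(max(abs(r$corrected)), 1e-6)
  expect_equal(r$baseline, rep(7, 200), tolerance = 1e-9)
})

test_that("SNIP defaults to 80 clipping iterations", {
  expect_identical(formals(snip_baseline)$iterations, 80L)
})

test_that("SNIP recovers a Lorentzian peak sitting on a linear ramp", {
  n <- 500
  ramp <- seq(0, 100, length.out = n)
  idx <- seq_len(n)
  peak <- 50 * 25 / ((idx - 250)^2 + 25)  # amp 50, fwhm 10
  r <- snip_baseline(ramp + peak, iterations = 80)
  expect_lt(abs(r$corrected[250] - 50) / 50, 0.05)  # apex within 5%
  far <- abs(idx - 250) > 5 * 10
  expect_lt(max(abs(r$corrected[far])), 1)          # flat far field
})

test_that("SNIP matches the literal clipping-loop oracle elementwise", {
  set.seed(21)
  for (rep_i in 1:20) {
    n <- sample(50:512, 1)
    base <- abs(rnorm(1, 20, 5)) + seq(0, rnorm(1, 10, 3), length.out = n)
    y <- base + abs(rnorm(n, 0, 1))
    it <- sample(c(5L, 20L, 80L), 1)
    ours <- snip_baseline(y, it)
    orac <- snip_oracle(y, it)
    expect_lt(max(abs(ours$baseline - orac$baseline)), 1e-9)
    # LLS-compressed variant agrees with its oracle too
    ours_lls <- snip_baseline(y, it, lls = TRUE)
    orac_lls <- snip_oracle(y, it, lls = TRUE)
    expect_lt(max(abs(ours_lls$baseline - orac_lls$baseline)), 1e-9)
  }
})

test_that("SNIP baseline never exceeds the spectrum", {
  set.seed(5)
  y <- abs(rnorm(300, 10, 3))
  r <- snip_baseline(y, 50)
  expect_true(all(r$baseline <= y + 1e-9))
  r2 <- snip_baseline(y, 50, decreasing = TRUE)
  expect_true(all(r2$baseline <= y + 1e-9))
})

test_that("SNIP rejects invalid input", {
  expect_error(snip_baseline(numeric(0)), "empty")
  expect_error(snip_baseline(1:10, iterations = 0), ">= 1")
})

test_that("L2 normalization follows the Euclidean-norm definition", {
  expect_equal(l2_normalize(c(3, 4)), c(0.6, 0.8))
  u <- c(1, 2, 2) / 3
  expect_equal(l2_normalize(u), u, tolerance = 1e-12)  # idempotent on unit sphere
  expect_error(l2_normalize(c(0, 0, 0)), "zero-norm")
})

test_that("L2 normalization is scale invariant with unit output norm", {
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(sample(5:200, 1))
    cx <- runif(1, 0.01, 100)
    expect_equal(sqrt(sum(l2_normalize(x)^2)), 1, tolerance = 1e-12)
    expect_equal(l2_normalize(cx * x), l2_normalize(x), tolerance = 1e-12)
  }
})

test_that("SNV normalization centers and scales by the population sd", {
  out <- snv_normalize(c(1, 2, 3))
  expect_equal(out, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  set.seed(8)
  x <- rnorm(100, 50, 4)
  s <- snv_normalize(x)
  expect_lt(abs(mean(s)), 1e-9)
  expect_equal(sqrt(mean((s - mean(s))^2)), 1, tolerance = 1e-9)
  expect_error(snv_normalize(c(5, 5, 5)), "zero-variance")
})

test_that("median filter follows the reflect-padded sliding median", {
  expect_equal(median_filter(c(1, 2, 100, 3, 4), 5), c(2, 2, 3, 3, 4))
  expect_equal(median_filter(rep(3.5, 30), 5), rep(3.5, 30))
  expect_identical(formals(median_filter)$window, 5L)
  expect_error(median_filter(1:10, 4), "odd")
  expect_error(median_filter(1:4, 7), "exceeds")
})

test_that("median filter removes isolated spikes flanked by clean samples", {
  set.seed(13)
  for (i in 1:10) {
    n <- 60
    x <- sin(seq(0, 4, length.out = n)) + 2
    pos <- sample(3:(n - 2), 1)
    spiked <- x
    spiked[pos] <- x[pos] + 50
    filt <- median_filter(spiked, 5)
    expect_lt(abs(filt[pos] - x[pos]), 0.2)
    expect_length(filt, n)
  }
})

test_that("Savitzky-Golay smoothing reproduces polynomials up to its order", {
  t <- seq(-1, 1, length.out = 50)
  y <- 2 + 0.5 * t - 3 * t^2 + 1.5 * t^3
  out <- smooth_spectrum(y, "savgol", window = 11, polyorder = 3)
  interior <- 10:41
  expect_equal(out[interior], y[interior], tolerance = 1e-8)
  expect_error(smooth_spectrum(y, "savgol", window = 11, polyorder = 11),
               "polyorder")
})

test_that("Gaussian smoothing of a unit impulse returns the normalized kernel", {
  n <- 41
  x <- numeric(n); x[21] <- 1
  sigma <- 2
  out <- smooth_spectrum(x, "gaussian", sigma = sigma)
  r <- ceiling(4 * sigma)
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  for (off in -2:2)
    expect_equal(out[21 + off], kern[r + 1 + off], tolerance = 1e-12)
})

test_that("both smoothers preserve constants", {
  x <- rep(4.2, 40)
  expect_equal(smooth_spectrum(x, "savgol"), x, tolerance = 1e-10)
  expect_equal(smooth_spectrum(x, "gaussian"), x, tolerance = 1e-10)
})
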