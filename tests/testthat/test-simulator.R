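test_that("Lorentzian lineshape matches its analytic maximum and half maximum", {
  axis <- seq(-10, 10, by = 1)   # centre on-grid
  peaks <- data.frame(amplitude = 1, center = 0, linewidth = 1)
  y <- lorentzian_profile(peaks, axis)
  expect_equal(y[axis == 0], 1)              # A / Gamma at resonance
  expect_equal(y[axis == 1], 0.5)            # half maximum at Omega + Gamma
  expect_equal(y[axis == -1], 0.5)           # ... and Omega - Gamma: FWHM = 2 Gamma
  expect_true(all(y > 0))
})

test_that("Lorentzian profile equals complex-susceptibility evaluation point by point", {
  axis <- wavenumber_axis(301L, 400, 1600)
  set.seed(11)
  peaks <- data.frame(amplitude = runif(7, 0.5, 5),
                      center = runif(7, 500, 1500),
                      linewidth = runif(7, 3, 40))
  y <- lorentzian_profile(peaks, axis)
  oracle <- rowSums(vapply(seq_len(nrow(peaks)), function(i) {
    chi <- peaks$amplitude[i] /
      (peaks$center[i] - axis - 1i * peaks$linewidth[i])
    Im(chi)
  }, numeric(length(axis))))
  expect_equal(y, oracle, tolerance = 1e-12)
})

test_that("Lorentzian profile rejects degenerate inputs", {
  axis <- wavenumber_axis(50L)
  expect_error(lorentzian_profile(data.frame(), axis), "non-empty")
  expect_error(lorentzian_profile(
    data.frame(amplitude = 1, center = 500, linewidth = -1), axis), "linewidth")
  expect_error(lorentzian_profile(
    data.frame(amplitude = -1, center = 500, linewidth = 1), axis), "amplitude")
  expect_error(lorentzian_profile(
    data.frame(amplitude = 1, center = 9000, linewidth = 1), axis), "inside")
})

test_that("scale_to_max rescales linearly and preserves the shape", {
  x <- c(0.5, 2, 1, 0.25)
  y <- scale_to_max(x, 4000)
  expect_equal(y, x * 2000)
  expect_equal(max(y), 4000)
  expect_equal(which.max(y), which.max(x))
  expect_equal(scale_to_max(x, max(x)), x)
  expect_error(scale_to_max(rep(0, 5), 10), "positive")
})

test_that("shot noise has Poisson moments and is reproducible", {
  expect_equal(add_shot_noise(rep(0, 100), seed = 1), rep(0, 100))
  lambda <- 4000
  n <- 1e5
  z <- add_shot_noise(rep(lambda, n), seed = 99)
  expect_lt(abs(mean(z) - lambda), 3 * sqrt(lambda / n))
  expect_lt(abs(var(z) - lambda) / lambda, 0.05)
  expect_identical(add_shot_noise(1:50 * 10, seed = 7),
                   add_shot_noise(1:50 * 10, seed = 7))
  expect_error(add_shot_noise(c(1, -2, 3)), "non-negative")
})

test_that("peak region finder recovers the FWHM window of a known Lorentzian", {
  # Gamma = 3 axis steps -> FWHM = 6 samples -> half width n = 3
  axis <- seq_len(201) - 101   # unit step, centre exactly on-grid at 0
  y <- lorentzian_profile(data.frame(amplitude = 3, center = 0, linewidth = 3),
                          axis)
  reg <- locate_peak_region(y)
  expect_equal(reg$peak_index, 101L)
  expect_equal(reg$half_width, 3L)
})

test_that("peak region finder picks the most prominent of several peaks", {
  axis <- seq_len(400)
  y <- lorentzian_profile(data.frame(amplitude = c(5, 20),
                                     center = c(100, 300),
                                     linewidth = c(5, 10)), axis)
  reg <- locate_peak_region(y)
  expect_equal(reg$peak_index, 300L)
})

test_that("peak window is clipped at the spectrum boundary", {
  axis <- seq_len(100)
  y <- lorentzian_profile(data.frame(amplitude = 50, center = 3, linewidth = 10),
                          axis)
  reg <- locate_peak_region(y)
  expect_gte(reg$peak_index - reg$half_width, 1L)
  expect_lte(reg$peak_index + reg$half_width, 100L)
  expect_error(locate_peak_region(rep(2, 50)), "constant")
})

test_that("dataset generation is reproducible and annotated consistently", {
  cfg <- sim_config(seed = 5L)
  d1 <- generate_dataset(cfg, 20L)
  d2 <- generate_dataset(cfg, 20L)
  expect_identical(d1, d2)
  expect_equal(dim(d1$clean), c(20L, 600L))
  expect_true(all(d1$clean > 0))
  expect_true(all(d1$noisy >= 0))
  expect_true(all(d1$noisy == round(d1$noisy)))   # Poisson counts
  for (s in c(1L, 7L, 20L)) {
    p <- d1$clean[s, ]
    expect_equal(d1$annotations$peak_index[s], which.max(p))
    expect_equal(d1$annotations$snr[s], global_snr(d1$noisy[s, ], p))
  }
  # RNG state of the caller must be untouched
  set.seed(123); before <- runif(3)
  generate_dataset(cfg, 2L)
  set.seed(123); expect_identical(runif(3), before)
})

test_that("default configuration spans narrow and broad spectral profiles", {
  ds <- generate_dataset(sim_config(seed = 77L), 300L)
  hw <- ds$annotations$half_width
  expect_gt(max(hw) / min(hw), 3)    # sharp chemical-like and broad
  expect_gt(stats::sd(hw), 2)        # biological-like windows both occur
})
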