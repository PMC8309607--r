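test_that("rmse matches an elementwise loop oracle and is symmetric", {
  set.seed(21)
  a <- runif(600, 0, 100); b <- runif(600, 0, 100)
  loop <- sqrt(sum((a - b)^2) / 600)
  expect_equal(rmse(a, b), loop, tolerance = 1e-12)
  expect_identical(rmse(a, b), rmse(b, a))
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, a + 2), 2)
  expect_error(rmse(a, b[-1]), "length")
})

test_that("global SNR is reference max over rmse, with an infinity sentinel", {
  ref <- c(rep(10, 99), 100)
  expect_equal(global_snr(ref + 2, ref), 100 / 2)
  expect_identical(global_snr(ref, ref), Inf)
  expect_error(global_snr(ref, rep(0, 100)), "positive")
  # not symmetric: the reference supplies the numerator
  noisy <- ref + rnorm(100)
  expect_false(isTRUE(all.equal(global_snr(noisy, ref), global_snr(ref, noisy))))
})

test_that("peak SNR restricts the error to the window but keeps the global max", {
  set.seed(4)
  ref <- lorentzian_profile(
    data.frame(amplitude = 40, center = 300, linewidth = 12), seq_len(600))
  ref <- scale_to_max(ref, 1000)
  noisy <- add_shot_noise(ref, seed = 8)
  reg <- peak_region(300L, 6L, 600L)          # the 13-sample comparison window
  idx <- 294:306
  oracle <- max(ref) / sqrt(mean((noisy[idx] - ref[idx])^2))
  expect_equal(peak_snr(noisy, ref, reg), oracle, tolerance = 1e-12)
  # a window covering the full support reduces exactly to the global SNR
  ref_odd <- lorentzian_profile(
    data.frame(amplitude = 20, center = 301, linewidth = 9), seq_len(601))
  noisy_odd <- add_shot_noise(scale_to_max(ref_odd, 900), seed = 12)
  ref_odd <- scale_to_max(ref_odd, 900)
  full <- peak_region(301L, 300L, 601L)
  expect_equal(peak_snr(noisy_odd, ref_odd, full),
               global_snr(noisy_odd, ref_odd), tolerance = 1e-15)
  # zero error inside the window while errors remain outside
  den <- noisy; den[idx] <- ref[idx]
  expect_identical(peak_snr(den, ref, reg), Inf)
  expect_true(is.finite(global_snr(den, ref)))
  expect_error(peak_snr(noisy, ref, peak_region(5L, 10L)), "window")
})

test_that("SNR product is 1 for identity, infinite for the oracle, < 1 when degrading", {
  set.seed(9)
  ref <- scale_to_max(lorentzian_profile(
    data.frame(amplitude = c(10, 30), center = c(150, 400), linewidth = c(8, 20)),
    seq_len(600)), 800)
  raw <- add_shot_noise(ref, seed = 3)
  reg <- locate_peak_region(ref)
  expect_equal(snr_product(raw, raw, ref, reg), 1)
  expect_identical(snr_product(ref, raw, ref, reg), Inf)
  worse <- raw + rnorm(600, sd = 3 * sqrt(mean(ref)))
  direct <- (global_snr(worse, ref) / global_snr(raw, ref)) *
    (peak_snr(worse, ref, reg) / peak_snr(raw, ref, reg))
  expect_equal(snr_product(worse, raw, ref, reg), direct, tolerance = 1e-12)
  expect_lt(snr_product(worse, raw, ref, reg), 1)
  expect_error(snr_product(raw, ref, ref, reg), "infinite")
})

test_that("all SNR metrics are invariant to a common positive rescaling", {
  set.seed(31)
  ref <- scale_to_max(lorentzian_profile(
    data.frame(amplitude = 5, center = 250, linewidth = 15), seq_len(600)), 500)
  raw <- add_shot_noise(ref, seed = 5)
  den <- savitzky_golay(raw)
  reg <- locate_peak_region(ref)
  for (c in c(0.01, 3.7, 1000)) {
    expect_equal(global_snr(den * c, ref * c), global_snr(den, ref))
    expect_equal(peak_snr(den * c, ref * c, reg), peak_snr(den, ref, reg))
    expect_equal(snr_product(den * c, raw * c, ref * c, reg),
                 snr_product(den, raw, ref, reg))
  }
})

test_that("snr_report rows and the table writer round-trip", {
  ref <- scale_to_max(lorentzian_profile(
    data.frame(amplitude = 5, center = 100, linewidth = 10), seq_len(300)), 600)
  raw <- add_shot_noise(ref, seed = 2)
  reg <- locate_peak_region(ref)
  rep1 <- snr_report(savitzky_golay(raw), raw, ref, reg)
  expect_named(rep1, c("global_snr_raw", "global_snr_denoised", "peak_snr_raw",
                       "peak_snr_denoised", "snr_product", "peak_index",
                       "half_width"))
  path <- tempfile(fileext = ".tsv")
  write_snr_table(rbind(rep1, rep1), path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 3L)              # two rows plus the mean row
  expect_equal(tab$id[3L], "mean")
  expect_equal(as.numeric(tab$snr_product[3L]), rep1$snr_product,
               tolerance = 1e-6)
})
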