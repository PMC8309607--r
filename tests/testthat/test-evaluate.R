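test_that("identity denoiser scores exactly 1 in every ratio column", {
  ds <- generate_dataset(sim_config(seed = 51L), 12L)
  ev <- evaluate_denoiser(identity, ds, name = "identity")
  expect_equal(ev$table$mean_global_improvement, 1)
  expect_equal(ev$table$mean_peak_improvement, 1)
  expect_equal(ev$table$mean_snr_product, 1)
  expect_equal(ev$table$n, 12L)
  expect_true(all(ev$per_spectrum$snr_product == 1))
})

test_that("oracle denoiser returns infinity sentinels, reported as such", {
  ds <- generate_dataset(sim_config(seed = 52L), 6L)
  oracle_by_id <- local({
    i <- 0L
    function(x) { i <<- i + 1L; ds$clean[i, ] }
  })
  ev <- evaluate_denoiser(oracle_by_id, ds, name = "oracle")
  expect_true(all(is.infinite(ev$per_spectrum$snr_product)))
  expect_identical(ev$table$mean_snr_product, Inf)
})

test_that("evaluation is a pure function of its inputs", {
  ds <- generate_dataset(sim_config(seed = 53L), 10L)
  e1 <- evaluate_denoiser(sg_denoiser("SG39"), ds, name = "SG39")
  e2 <- evaluate_denoiser(sg_denoiser("SG39"), ds, name = "SG39")
  expect_identical(e1, e2)
  # malformed denoiser output is rejected
  expect_error(evaluate_denoiser(function(x) x[-1], ds), "600")
})

test_that("peak windows honour the fixed 13-sample default and the annotations", {
  ds <- generate_dataset(sim_config(seed = 54L), 5L)
  ev <- evaluate_denoiser(identity, ds, fixed_window = 13L)
  expect_true(all(ev$per_spectrum$half_width <= 6L))
  ev_ann <- evaluate_denoiser(identity, ds, fixed_window = NULL)
  expect_equal(ev_ann$per_spectrum$half_width, ds$annotations$half_width)
  expect_error(evaluate_denoiser(identity, ds, fixed_window = 12L), "odd")
})

test_that("binned generation matches requested mean SNR targets", {
  bins <- binned_datasets(sim_config(seed = 55L), c(25, 40), n_per_bin = 25L)
  expect_length(bins, 2L)
  for (i in 1:2) {
    target <- c(25, 40)[i]
    achieved <- mean(bins[[i]]$annotations$snr)
    expect_lt(abs(achieved - target) / target, 0.1)
    expect_equal(attr(bins[[i]], "achieved_snr"), achieved)
  }
  bins2 <- binned_datasets(sim_config(seed = 55L), c(25, 40), n_per_bin = 25L)
  expect_identical(bins, bins2)
  single <- binned_datasets(sim_config(seed = 56L), 30, n_per_bin = 1L)
  expect_equal(nrow(single[[1]]$clean), 1L)
  expect_error(binned_datasets(sim_config(seed = 57L), 1e6), "not reachable")
})

test_that("a weighting sweep trains one model per alpha on identical data", {
  cfg <- tiny_sim_config(seed = 61L)
  test_data <- generate_dataset(tiny_sim_config(seed = 62L), 15L)
  tc <- train_config(n_epochs = 2L, lr_halving_epoch = 2L, batch_size = 16L,
                     seed = 1L)
  tab <- alpha_sweep(c(0, 50), cfg, tc, test_data, net_spec = tiny_spec(),
                     train_size = 32L, val_size = 8L, fixed_window = 5L)
  expect_equal(tab$alpha, c(0, 50))
  expect_true(all(is.finite(tab$mean_snr_product)))
  one <- alpha_sweep(7, cfg, tc, test_data, net_spec = tiny_spec(),
                     train_size = 32L, val_size = 8L, fixed_window = 5L)
  expect_equal(nrow(one), 1L)
})
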