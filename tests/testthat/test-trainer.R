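test_that("batch bookkeeping uses ceiling division", {
  expect_identical(batches_per_epoch(10000, 128), 79L)
  expect_identical(batches_per_epoch(128, 128), 1L)
  expect_identical(batches_per_epoch(129, 128), 2L)
  expect_identical(batches_per_epoch(1, 128), 1L)
  expect_error(batches_per_epoch(100, 0), "positive")
})

test_that("learning rate halves exactly after the halving epoch", {
  cfg <- train_config()
  expect_identical(lr_schedule(1, cfg), 1e-9)
  expect_identical(lr_schedule(50, cfg), 1e-9)
  expect_identical(lr_schedule(51, cfg), 5e-10)
  expect_identical(lr_schedule(100, cfg), 5e-10)
  expect_error(lr_schedule(101, cfg), "1..100")
  expect_error(lr_schedule(0, cfg), "1..100")
  expect_error(train_config(lr_halving_epoch = 60, n_epochs = 50), "exceed")
})

test_that("training records consistent loss histories and is reproducible", {
  train <- generate_dataset(tiny_sim_config(seed = 1L), 70L)
  val <- generate_dataset(tiny_sim_config(seed = 2L), 13L)
  cfg <- train_config(n_epochs = 3L, lr_halving_epoch = 2L, batch_size = 32L,
                      alpha = 50, seed = 9L)
  run1 <- train_network(build_network(tiny_spec(), seed = 4L), train, val, cfg)
  run2 <- train_network(build_network(tiny_spec(), seed = 4L), train, val, cfg)
  expect_identical(run1$history, run2$history)
  expect_identical(run1$model$layers, run2$model$layers)
  expect_length(run1$history$per_batch_train_loss,
                3L * batches_per_epoch(70L, 32L))
  expect_length(run1$history$per_epoch_val_loss, 3L)
  expect_length(run1$history$per_epoch_val_mse, 3L)
  expect_equal(run1$history$lr, c(1e-9, 1e-9, 5e-10))
  expect_true(all(is.finite(run1$history$per_batch_train_loss)))
  expect_true(all(run1$history$per_epoch_val_loss > 0))
  expect_true(isTRUE(run1$model$trained))
  # a different shuffling seed changes the trajectory
  cfg2 <- cfg; cfg2$seed <- 10L
  run3 <- train_network(build_network(tiny_spec(), seed = 4L), train, val, cfg2)
  expect_false(identical(run1$history$per_batch_train_loss,
                         run3$history$per_batch_train_loss))
  expect_error(train_network(build_network(seed = 1), train, val, cfg), "expects")
})

test_that("loss-curve smoothing reproduces polynomials and reduces noise", {
  expect_equal(smooth_loss_curve(rep(3, 50)), rep(3, 50))
  x <- seq(0, 1, length.out = 80)
  cubic <- 2 - x + 0.5 * x^2 + 4 * x^3
  sm <- smooth_loss_curve(cubic)
  interior <- 15:66
  expect_equal(sm[interior], cubic[interior], tolerance = 1e-9)
  set.seed(6)
  noisy <- cubic + rnorm(80, sd = 0.3)
  expect_lt(var(smooth_loss_curve(noisy) - cubic), var(noisy - cubic))
  expect_error(smooth_loss_curve(rep(1, 29)), "longer")
})

test_that("a training run directory snapshots config, history and checkpoint", {
  train <- generate_dataset(tiny_sim_config(seed = 3L), 40L)
  val <- generate_dataset(tiny_sim_config(seed = 4L), 10L)
  cfg <- train_config(n_epochs = 2L, lr_halving_epoch = 1L, batch_size = 20L,
                      seed = 1L)
  fit <- train_network(build_network(tiny_spec(), seed = 2L), train, val, cfg)
  dir <- file.path(tempdir(), "run-test")
  save_run(fit, dir)
  expect_setequal(list.files(dir),
                  c("config.json", "history.tsv", "val_history.tsv",
                    "model.rds", "model.rds.json", "run.log"))
  snap <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(snap$n_epochs, 2L)
  expect_equal(snap$alpha, 50)
  hist <- read.delim(file.path(dir, "history.tsv"))
  expect_equal(nrow(hist), 2L * batches_per_epoch(40L, 20L))
  vh <- read.delim(file.path(dir, "val_history.tsv"))
  expect_equal(vh$lr, c(1e-9, 5e-10))
  reloaded <- load_model(file.path(dir, "model.rds"))
  expect_identical(reloaded$layers, fit$model$layers)
})
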