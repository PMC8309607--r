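#' Training configuration
#'
#' Optimization settings for [train_network()]: plain stochastic gradient
#' descent with momentum 0.9, mini-batches of 128 spectra, 100 epochs with
#' the learning rate halved after epoch 50, and an initial learning rate of
#' 1e-9. The learning rate is calibrated for spectra standardized by
#' `intensity_scale` and for the summed-squared-error objective (see
#' `objective`); change either convention and the rate must change with it.
#' For training runs much shorter than the default 100-epoch schedule,
#' scale the rate so that the product of learning rate and total update
#' steps matches the full schedule (compute-matched scaling).
#'
#' @param initial_lr Initial learning rate (default `1e-9`).
#' @param momentum SGD momentum in (0, 1) (default 0.9).
#' @param batch_size Mini-batch size (default 128).
#' @param n_epochs Number of training epochs (default 100).
#' @param lr_halving_epoch Last epoch at the full rate; epochs
#'   `lr_halving_epoch + 1` onwards use half of it (default 50).
#' @param alpha Peak weighting of the loss (default 50; see [custom_loss()]).
#' @param objective Reduction convention of the training objective:
#'   `"sum"` (default) optimizes the summed squared error over the batch
#'   (per-spectrum summed over the samples), the convention the default
#'   learning rate is calibrated for; `"mean"` optimizes the batch mean of
#'   the mean-form loss. Both record the mean-form [custom_loss()] (on the
#'   original intensity scale) in the history.
#' @param intensity_scale Fixed factor by which spectra are divided before
#'   entering the network (default 4000, the design maximum intensity of
#'   the simulator). Standardizing to the unit scale is what makes the
#'   published learning rate effective; set to 1 to train on raw counts.
#' @param train_size,val_size Default split sizes used by the command-line
#'   `train` subcommand when it simulates its own data (10,000 each).
#' @param seed Integer seed controlling the batch shuffling order.
#' @return An object of class `train_config`.
#' @export
train_config <- function(initial_lr = 1e-9, momentum = 0.9, batch_size = 128L,
                         n_epochs = 100L, lr_halving_epoch = 50L, alpha = 50,
                         objective = c("sum", "mean"), intensity_scale = 4000,
                         train_size = 10000L, val_size = 10000L, seed = 1L) {
  objective <- match.arg(objective)
  if (!is.numeric(initial_lr) || initial_lr <= 0) stop("'initial_lr' must be positive")
  if (!is.numeric(momentum) || momentum <= 0 || momentum >= 1)
    stop("'momentum' must be in (0, 1)")
  batch_size <- as.integer(batch_size)
  n_epochs <- as.integer(n_epochs)
  lr_halving_epoch <- as.integer(lr_halving_epoch)
  if (batch_size < 1L) stop("'batch_size' must be positive")
  if (n_epochs < 1L) stop("'n_epochs' must be positive")
  if (lr_halving_epoch > n_epochs)
    stop("'lr_halving_epoch' cannot exceed 'n_epochs'")
  if (!is.numeric(alpha) || alpha < 0) stop("'alpha' must be non-negative")
  if (!is.numeric(intensity_scale) || intensity_scale <= 0)
    stop("'intensity_scale' must be positive")
  structure(list(initial_lr = initial_lr, momentum = momentum,
                 batch_size = batch_size, n_epochs = n_epochs,
                 lr_halving_epoch = lr_halving_epoch, alpha = alpha,
                 objective = objective, intensity_scale = intensity_scale,
                 train_size = as.integer(train_size),
                 val_size = as.integer(val_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Number of mini-batches per epoch
#'
#' Ceiling division: the last, possibly smaller, batch counts. With the
#' default 10,000 training spectra and batch size 128 this gives 79 batches
#' (78 full batches plus one of 16).
#'
#' @param n_samples Number of training spectra.
#' @param batch_size Mini-batch size.
#' @return Integer batch count.
#' @export
batches_per_epoch <- function(n_samples, batch_size) {
  n_samples <- as.integer(n_samples)
  batch_size <- as.integer(batch_size)
  if (is.na(batch_size) || batch_size < 1L) stop("'batch_size' must be a positive integer")
  if (is.na(n_samples) || n_samples < 1L) stop("'n_samples' must be a positive integer")
  as.integer(ceiling(n_samples / batch_size))
}

#' Stepped learning-rate schedule
#'
#' The full `initial_lr` for epochs `1..lr_halving_epoch`, and exactly half
#' of it from the next epoch to the end.
#'
#' @param epoch Epoch number (1-based).
#' @param config A [train_config()].
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config) {
  if (!inherits(config, "train_config")) stop("'config' must be a train_config")
  epoch <- as.integer(epoch)
  if (any(is.na(epoch)) || any(epoch < 1L) || any(epoch > config$n_epochs))
    stop(sprintf("'epoch' must be in 1..%d", config$n_epochs))
  ifelse(epoch <= config$lr_halving_epoch, config$initial_lr, config$initial_lr / 2)
}

dataset_matrices <- function(dataset) {
  if (!inherits(dataset, "raman_dataset")) stop("expected a raman_dataset")
  list(X = t(dataset$noisy), Y = t(dataset$clean),
       pk = as.integer(dataset$annotations$peak_index),
       nw = as.integer(dataset$annotations$half_width))
}

#' Train the denoising network
#'
#' Mini-batch SGD with momentum on (noisy input, clean target) pairs,
#' minimizing the peak-weighted loss with each pair's precomputed peak
#' window (annotated on the clean spectrum at generation time). The
#' training order is reshuffled every epoch from `config$seed`, the
#' per-batch training loss is recorded, and at the end of every epoch the
#' mean validation loss (both the peak-weighted loss and the plain MSE) is
#' computed in inference mode. Fully reproducible for a fixed seed.
#'
#' @param model An untrained (or previously trained) [build_network()] model.
#' @param train_data,val_data [generate_dataset()] objects (or objects read
#'   back by [read_dataset()]).
#' @param config A [train_config()].
#' @return A list with `model` (the trained network, with `train_config`
#'   attached) and `history` (class `loss_history`): `per_batch_train_loss`,
#'   `per_epoch_val_loss`, `per_epoch_val_mse`, `lr` per epoch.
#' @export
train_network <- function(model, train_data, val_data, config = train_config()) {
  if (!inherits(model, "raman_cnn")) stop("'model' must be a raman_cnn")
  if (!inherits(config, "train_config")) stop("'config' must be a train_config")
  tr <- dataset_matrices(train_data)
  va <- dataset_matrices(val_data)
  if (nrow(tr$X) != model$spec$input_length || nrow(va$X) != model$spec$input_length)
    stop(sprintf("dataset spectra have %d samples but the network expects %d",
                 nrow(tr$X), model$spec$input_length))
  if (ncol(tr$X) == 0L || ncol(va$X) == 0L) stop("training and validation sets must be non-empty")
  if (config$intensity_scale == 1 && config$initial_lr < 1e-6 &&
      max(tr$Y) > 100)
    warning("training on raw intensities with a learning rate calibrated ",
            "for unit-scale inputs; consider the default intensity_scale")
  sc <- config$intensity_scale
  fit <- cpp_cnn_train(model$layers, tr$X / sc, tr$Y / sc, tr$pk, tr$nw,
                       va$X / sc, va$Y / sc, va$pk, va$nw,
                       config$alpha, config$initial_lr, config$momentum,
                       config$batch_size, config$n_epochs,
                       config$lr_halving_epoch, config$seed,
                       config$objective == "sum")
  model$layers <- fit$layers
  model$trained <- TRUE
  model$train_config <- config
  model$input_scale <- sc
  history <- structure(list(
    per_batch_train_loss = as.numeric(fit$train_loss) * sc^2,
    per_epoch_val_loss = as.numeric(fit$val_loss) * sc^2,
    per_epoch_val_mse = as.numeric(fit$val_mse) * sc^2,
    lr = lr_schedule(seq_len(config$n_epochs), config)
  ), class = "loss_history")
  list(model = model, history = history)
}

#' @export
print.loss_history <- function(x, ...) {
  cat(sprintf("<loss_history> %d batches over %d epochs; val loss %.4g -> %.4g\n",
              length(x$per_batch_train_loss), length(x$per_epoch_val_loss),
              x$per_epoch_val_loss[1L],
              x$per_epoch_val_loss[length(x$per_epoch_val_loss)]))
  invisible(x)
}

#' Smooth a per-batch loss curve for plotting
#'
#' Savitzky--Golay smoothing with window 29 and polynomial order 3, the
#' setting used for displaying training-loss traces.
#'
#' @param x Numeric series (e.g. `history$per_batch_train_loss`), longer
#'   than 29 samples.
#' @return Smoothed numeric series of the same length.
#' @export
smooth_loss_curve <- function(x) {
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (length(x) <= 29L) stop("loss series must be longer than 29 samples")
  savitzky_golay(x, sg_config(29L, 3L))
}

#' Save a training run to a directory
#'
#' Writes the artifacts of one [train_network()] run: a config snapshot
#' (`config.json`), the loss history (`history.tsv`: batch losses;
#' `val_history.tsv`: per-epoch validation losses and learning rates), the
#' model checkpoint (`model.rds` + provenance sidecar) and a line-oriented
#' log (`run.log`).
#'
#' @param fit The list returned by [train_network()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_run <- function(fit, dir) {
  stopifnot(is.list(fit), inherits(fit$model, "raman_cnn"),
            inherits(fit$history, "loss_history"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- fit$model$train_config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  data.table::fwrite(data.frame(batch = seq_along(fit$history$per_batch_train_loss),
                                train_loss = fit$history$per_batch_train_loss),
                     file.path(dir, "history.tsv"), sep = "\t")
  data.table::fwrite(data.frame(epoch = seq_along(fit$history$per_epoch_val_loss),
                                lr = fit$history$lr,
                                val_loss = fit$history$per_epoch_val_loss,
                                val_mse = fit$history$per_epoch_val_mse),
                     file.path(dir, "val_history.tsv"), sep = "\t")
  save_model(fit$model, file.path(dir, "model.rds"))
  log_lines <- sprintf("%s epoch=%d lr=%.3g val_loss=%.6g val_mse=%.6g",
                       format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                       seq_along(fit$history$per_epoch_val_loss),
                       fit$history$lr, fit$history$per_epoch_val_loss,
                       fit$history$per_epoch_val_mse)
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}
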