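# Shared fixtures and independent oracles. Heavy objects (the large
# calibration dataset, the scaled-down trainings) are computed once per test
# run and cached here so several test files can share them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# A three-unit miniature of the real architecture: cheap enough for
# finite-difference checks, still covering all conv code paths (small even
# and odd kernels plus a width-5 unit) and batch norm.
tiny_spec <- function() {
  network_spec(input_length = 24L, n_filters = c(4L, 3L, 1L),
               filter_widths = c(3L, 4L, 5L))
}

# A variant whose width-5 unit has enough channels to engage the Winograd
# fast-convolution schedule (channels x width > 16), so the gradient and
# parity oracles cover that path explicitly.
wino_spec <- function() {
  network_spec(input_length = 24L, n_filters = c(6L, 3L, 1L),
               filter_widths = c(3L, 5L, 4L))
}

# Simulator settings usable at 24 samples (for fast trainer tests).
tiny_sim_config <- function(seed = 1L) {
  sim_config(n_samples = 24L, n_peaks_range = c(2L, 4L),
             linewidth_range = c(1.5, 3), intensity_max_range = c(500, 4000),
             seed = seed)
}

# Reference forward pass written independently in plain R: direct "same"
# convolution, inference-mode batch norm, ReLU. Used as the oracle for the
# compiled forward pass (including its Winograd fast path).
ref_conv_same <- function(x, Wk) {
  k <- dim(Wk)[1]; Cout <- dim(Wk)[3]
  N <- nrow(x); pl <- (k - 1) %/% 2
  out <- matrix(0, N, Cout)
  for (o in seq_len(Cout)) for (i in seq_len(N)) {
    acc <- 0
    for (t in seq_len(k)) {
      src <- i + (t - 1) - pl
      if (src >= 1 && src <= N) acc <- acc + sum(Wk[t, , o] * x[src, ])
    }
    out[i, o] <- acc
  }
  out
}

ref_forward <- function(model, xvec) {
  x <- matrix(xvec, ncol = 1)
  for (l in model$layers) {
    z <- ref_conv_same(x, l$W)
    if (l$has_bn) {
      z <- sweep(z, 2, l$running_mean)
      z <- sweep(z, 2, sqrt(l$running_var + 1e-5), "/")
      z <- sweep(sweep(z, 2, l$gamma, "*"), 2, l$beta, "+")
      x <- pmax(z, 0)
    } else {
      x <- sweep(z, 2, l$b, "+")
    }
  }
  x[, 1]
}

# Large simulated dataset under the default calibrated configuration,
# shared by the calibration checks.
calibration_dataset <- function() {
  cached("calibration_dataset", generate_dataset(sim_config(seed = 424L), 10000L))
}

# Configuration for head-to-head denoiser comparison bins, emulating the
# published benchmark design: the peak fidelity of a *sharp* local feature
# is scored over a 13-sample window, so the evaluated spectra carry peaks
# whose FWHM (= 2 * linewidth, 3-6 samples) fits inside that window.
sharp_eval_config <- function(seed = 103L) {
  sim_config(n_peaks_range = c(5L, 12L), linewidth_range = c(1.5, 3),
             height_range = c(0.2, 1), seed = seed)
}

# Low-SNR sharp-feature bin (mean raw global SNR ~ 25) for the
# cross-filter comparisons.
low_snr_bin <- function() {
  cached("low_snr_bin",
         binned_datasets(sharp_eval_config(103L), 25, n_per_bin = 50L)[[1L]])
}

# Held-out low-SNR bin drawn from the training distribution (the default
# simulator configuration), for scoring trained networks.
held_out_bin <- function() {
  cached("held_out_bin",
         binned_datasets(sim_config(seed = 104L), 25, n_per_bin = 50L)[[1L]])
}

# The scaled-down supervised trainings (2000 pairs, 20 epochs) for the
# peak-weighted and plain-MSE objectives, trained identically.
scaled_down_fits <- function() {
  cached("scaled_down_fits", {
    train <- generate_dataset(sim_config(seed = 101L), 2000L)
    val <- generate_dataset(sim_config(seed = 102L), 200L)
    fits <- lapply(c(50, 0), function(a) {
      cfg <- train_config(n_epochs = 20L, lr_halving_epoch = 20L,
                          alpha = a, seed = 1L)
      train_network(build_network(seed = 1L), train, val, cfg)
    })
    names(fits) <- c("alpha50", "alpha0")
    fits
  })
}
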