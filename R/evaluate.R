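#' Evaluate a denoiser on a dataset of spectrum pairs
#'
#' Applies `denoiser` to every noisy spectrum and scores it against the
#' clean reference with the SNR metrics. By default the peak window is the
#' fixed 13-sample window (the peak maximum plus or minus 6 samples) used
#' for cross-denoiser comparisons; set `fixed_window = NULL` to use each
#' pair's annotated FWHM-adaptive window instead. Results are aggregated
#' per raw-SNR bin.
#'
#' @param denoiser A function mapping a numeric spectrum to its denoised
#'   version (e.g. [sg_denoiser()] or `function(x) denoise(model, x)`), or a
#'   `raman_cnn` model (denoised in one batched forward pass).
#' @param dataset A [generate_dataset()] object.
#' @param fixed_window Odd window length for the peak term (default 13), or
#'   `NULL` for the annotated per-pair windows.
#' @param snr_breaks Optional numeric break points for binning pairs by raw
#'   global SNR; default is a single bin spanning the whole dataset.
#' @param name Denoiser label used in the output table.
#' @return A list with `per_spectrum` (stacked [snr_report()] rows plus
#'   `id`, `raw_snr`, `bin`) and `table`, a data.frame keyed by
#'   (`denoiser`, `bin`) with the mean global-SNR improvement ratio, mean
#'   peak-SNR improvement ratio, mean SNR product and spectrum count.
#' @export
evaluate_denoiser <- function(denoiser, dataset, fixed_window = 13L,
                              snr_breaks = NULL, name = "denoiser") {
  if (!inherits(dataset, "raman_dataset")) stop("'dataset' must be a raman_dataset")
  n <- nrow(dataset$clean)
  if (n < 1L) stop("'dataset' is empty")
  ns <- ncol(dataset$clean)
  if (inherits(denoiser, "raman_cnn")) {
    model <- denoiser
    denoised <- denoise(model, dataset$noisy)
  } else {
    if (!is.function(denoiser)) stop("'denoiser' must be a function or a raman_cnn")
    denoised <- t(vapply(seq_len(n), function(s) {
      out <- denoiser(dataset$noisy[s, ])
      if (length(out) != ns)
        stop(sprintf("denoiser returned %d samples for a %d-sample spectrum",
                     length(out), ns))
      as.numeric(out)
    }, numeric(ns)))
  }
  if (!is.null(fixed_window)) {
    fixed_window <- as.integer(fixed_window)
    if (fixed_window < 3L || fixed_window %% 2L == 0L)
      stop("'fixed_window' must be an odd integer >= 3")
  }
  half <- if (is.null(fixed_window)) NULL else (fixed_window - 1L) %/% 2L
  rows <- do.call(rbind, lapply(seq_len(n), function(s) {
    p <- dataset_pair(dataset, s)
    reg <- if (is.null(half)) p$region else {
      pk <- p$region$peak_index
      peak_region(pk, min(half, pk - 1L, ns - pk), n_samples = ns)
    }
    snr_report(denoised[s, ], p$noisy, p$reference, reg)
  }))
  rows$id <- seq_len(n)
  rows$raw_snr <- dataset$annotations$snr
  if (is.null(snr_breaks)) {
    rows$bin <- sprintf("[%.3g,%.3g]", min(rows$raw_snr), max(rows$raw_snr))
  } else {
    rows$bin <- as.character(cut(rows$raw_snr, breaks = snr_breaks,
                                 include.lowest = TRUE))
  }
  agg <- do.call(rbind, lapply(split(rows, rows$bin), function(g) {
    data.frame(
      denoiser = name,
      bin = g$bin[1L],
      mean_raw_snr = mean(g$raw_snr),
      mean_global_improvement = mean(g$global_snr_denoised / g$global_snr_raw),
      mean_peak_improvement = mean(g$peak_snr_denoised / g$peak_snr_raw),
      mean_snr_product = mean(g$snr_product),
      n = nrow(g)
    )
  }))
  rownames(agg) <- NULL
  list(per_spectrum = rows, table = agg)
}

#' Sweep the peak weighting factor of the loss
#'
#' Trains one network per `alpha` on identical data (same simulated
#' training/validation sets, same initial weights and shuffling seed),
#' evaluates each on the same test pairs, and tabulates the mean SNR
#' product. This reproduces the weighting-sweep design used to select
#' `alpha = 50`: performance rises from `alpha = 0` (plain MSE) and
#' saturates around 50.
#'
#' @param alphas Weighting factors to sweep (default `c(0, 1, 10, 50, 100)`).
#' @param sim_config A [sim_config()] for the training/validation data.
#' @param train_config A [train_config()]; its `alpha` field is overridden
#'   by each swept value.
#' @param test_data A [generate_dataset()] object for evaluation.
#' @param net_spec Architecture to train (default [network_spec()]).
#' @param train_size,val_size Simulated split sizes.
#' @param fixed_window Peak window for evaluation (see [evaluate_denoiser()]).
#' @return data.frame with one row per alpha: mean SNR product and the mean
#'   improvement ratios on the test set.
#' @export
alpha_sweep <- function(alphas = c(0, 1, 10, 50, 100), sim_config,
                        train_config, test_data, net_spec = network_spec(),
                        train_size = 2000L, val_size = 500L,
                        fixed_window = 13L) {
  if (length(alphas) < 1L || any(alphas < 0)) stop("'alphas' must be non-negative")
  cfg_tr <- sim_config
  cfg_tr$seed <- sim_config$seed
  train_data <- generate_dataset(cfg_tr, train_size)
  cfg_va <- sim_config
  cfg_va$seed <- sim_config$seed + 1L
  val_data <- generate_dataset(cfg_va, val_size)
  rows <- lapply(alphas, function(a) {
    tc <- train_config
    tc$alpha <- a
    model <- build_network(net_spec, seed = train_config$seed)
    fit <- train_network(model, train_data, val_data, tc)
    ev <- evaluate_denoiser(fit$model, test_data, fixed_window = fixed_window,
                            name = sprintf("cnn_alpha_%g", a))
    data.frame(alpha = a,
               mean_snr_product = ev$table$mean_snr_product[1L],
               mean_global_improvement = ev$table$mean_global_improvement[1L],
               mean_peak_improvement = ev$table$mean_peak_improvement[1L])
  })
  do.call(rbind, rows)
}

#' Simulated dataset bins with prescribed mean SNR
#'
#' Emulates the graded-exposure evaluation design on synthetic data: for
#' each target, searches (by bisection on the clean spectra's maximum
#' intensity, which sets the shot-noise level) for a fixed intensity scale
#' whose generated pairs have a mean global SNR within 10 percent of the
#' target. Bins are seeded and reproducible; each bin records its achieved
#' mean SNR.
#'
#' @param sim_config A [sim_config()]; its `intensity_max_range` is
#'   overridden by the search.
#' @param snr_targets Target mean global SNRs (e.g. `c(15, 25, 40, 60)`).
#' @param n_per_bin Spectra per bin (default 50).
#' @return A list of `raman_dataset` bins with attributes `target_snr`,
#'   `achieved_snr` and `intensity_max`.
#' @export
binned_datasets <- function(sim_config, snr_targets, n_per_bin = 50L) {
  if (!inherits(sim_config, "sim_config")) stop("'sim_config' must be a sim_config")
  if (length(snr_targets) < 1L || any(snr_targets <= 0))
    stop("'snr_targets' must be positive")
  n_per_bin <- as.integer(n_per_bin)
  if (n_per_bin < 1L) stop("'n_per_bin' must be at least 1")
  gen_at <- function(m, seed) {
    cfg <- sim_config
    cfg$intensity_max_range <- c(m, m)
    cfg$seed <- seed
    generate_dataset(cfg, n_per_bin)
  }
  lapply(seq_along(snr_targets), function(i) {
    target <- snr_targets[i]
    seed <- sim_config$seed + i
    # mean SNR grows monotonically with the intensity scale (shot-noise
    # RMSE ~ sqrt(intensity)); bracket then bisect
    lo <- 1; hi <- 16000
    mean_at <- function(m) mean(gen_at(m, seed)$annotations$snr)
    if (mean_at(hi) < target || mean_at(lo) > target)
      stop(sprintf("target SNR %.3g is not reachable by intensity scaling", target))
    for (it in 1:40) {
      mid <- sqrt(lo * hi)
      v <- mean_at(mid)
      if (abs(v - target) / target < 0.02) { lo <- hi <- mid; break }
      if (v < target) lo <- mid else hi <- mid
      if (hi / lo < 1 + 1e-6) break
    }
    m <- sqrt(lo * hi)
    ds <- gen_at(m, seed)
    achieved <- mean(ds$annotations$snr)
    if (abs(achieved - target) / target > 0.1)
      stop(sprintf("could not match target SNR %.3g (achieved %.3g)", target, achieved))
    attr(ds, "target_snr") <- target
    attr(ds, "achieved_snr") <- achieved
    attr(ds, "intensity_max") <- m
    ds
  })
}
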