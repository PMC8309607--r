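#' Uniform wavenumber axis
#'
#' Builds the spectral axis on which all simulated spectra live: `n` uniformly
#' spaced wavenumber values. The default 600-sample axis spans a nominal
#' 400--2000 cm^-1 fingerprint region; since the simulator draws peak
#' positions and linewidths relative to the axis, the physical range is
#' cosmetic and only the number of samples matters.
#'
#' @param n Number of samples (default 600).
#' @param from,to Axis end points in cm^-1-like units, `from < to`.
#' @return Numeric vector of length `n`, strictly increasing, constant step.
#' @export
wavenumber_axis <- function(n = 600L, from = 400, to = 2000) {
  n <- as.integer(n)
  if (n < 2L) stop("axis needs at least 2 samples")
  if (!(from < to)) stop("'from' must be less than 'to'")
  seq(from, to, length.out = n)
}

axis_step <- function(axis) (axis[length(axis)] - axis[1L]) / (length(axis) - 1L)

validate_axis <- function(axis) {
  if (!is.numeric(axis) || length(axis) < 2L) stop("invalid wavenumber axis")
  d <- diff(axis)
  if (any(d <= 0)) stop("wavenumber axis must be strictly increasing")
  if (max(d) - min(d) > 1e-8 * mean(d)) stop("wavenumber axis must be uniformly spaced")
  invisible(axis)
}

#' Sum of Lorentzian lineshapes
#'
#' Evaluates the imaginary part of the complex Raman susceptibility
#' chi(w) = A / (Omega - w - i*Gamma) for each peak and sums over peaks:
#' Im chi = A * Gamma / ((Omega - w)^2 + Gamma^2). The profile peaks at
#' `amplitude / linewidth` when `w == center` and its full width at half
#' maximum is `2 * linewidth`.
#'
#' @param peaks data.frame with columns `amplitude` (A > 0), `center`
#'   (Omega, inside the axis range) and `linewidth` (Gamma > 0, axis units).
#' @param axis Wavenumber axis from [wavenumber_axis()].
#' @return Numeric intensity vector, strictly positive.
#' @export
lorentzian_profile <- function(peaks, axis) {
  validate_axis(axis)
  if (!is.data.frame(peaks) || nrow(peaks) == 0L)
    stop("'peaks' must be a non-empty data.frame")
  need <- c("amplitude", "center", "linewidth")
  if (!all(need %in% names(peaks)))
    stop("'peaks' needs columns amplitude, center, linewidth")
  if (any(peaks$amplitude <= 0)) stop("peak amplitudes must be positive")
  if (any(peaks$linewidth <= 0)) stop("peak linewidths must be positive")
  if (any(peaks$center < axis[1L] | peaks$center > axis[length(axis)]))
    stop("peak centers must lie inside the axis range")
  y <- numeric(length(axis))
  for (i in seq_len(nrow(peaks))) {
    A <- peaks$amplitude[i]; Om <- peaks$center[i]; G <- peaks$linewidth[i]
    y <- y + A * G / ((Om - axis)^2 + G^2)
  }
  y
}

#' Rescale a spectrum to a target maximum intensity
#'
#' Multiplies the whole spectrum by `target_max / max(x)` so its maximum
#' equals `target_max`; the shape (and the argmax position) is unchanged.
#'
#' @param x Numeric intensity vector with a positive maximum.
#' @param target_max Positive target for the new maximum.
#' @return Rescaled intensity vector.
#' @export
scale_to_max <- function(x, target_max) {
  if (!is.numeric(x) || length(x) == 0L) stop("'x' must be a numeric vector")
  m <- max(x)
  if (!is.finite(m) || m <= 0) stop("spectrum maximum must be positive")
  if (!is.numeric(target_max) || length(target_max) != 1L || target_max <= 0)
    stop("'target_max' must be a single positive number")
  x * (target_max / m)
}

#' Add Poisson shot noise to a spectrum
#'
#' Photon-counting (shot) noise: each channel of the output is an independent
#' Poisson draw whose mean is the clean intensity in that channel, so the
#' noise variance equals the local intensity.
#'
#' @param x Non-negative numeric intensity vector (expected photon counts).
#' @param seed Optional integer; when given, draws are reproducible and the
#'   caller's RNG state is left untouched.
#' @return Numeric vector of counts (integers stored as doubles).
#' @export
add_shot_noise <- function(x, seed = NULL) {
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (any(!is.finite(x)) || any(x < 0)) stop("intensities must be finite and non-negative")
  if (!is.null(seed)) {
    return(with_preserved_rng(seed, as.numeric(stats::rpois(length(x), x))))
  }
  as.numeric(stats::rpois(length(x), x))
}

# Run `expr` under set.seed(seed) and restore the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Peak region constructor
#'
#' A `peak_region` is the `2n + 1` sample window centred on the most
#' prominent peak of a spectrum: `peak_index` (1-based) and `half_width` n.
#'
#' @param peak_index Integer index of the window centre (1-based).
#' @param half_width Positive integer half width n.
#' @param n_samples Optional spectrum length; when supplied the window is
#'   checked to lie fully inside `[1, n_samples]`.
#' @return An object of class `peak_region`.
#' @export
peak_region <- function(peak_index, half_width, n_samples = NULL) {
  peak_index <- as.integer(peak_index)
  half_width <- as.integer(half_width)
  if (length(peak_index) != 1L || is.na(peak_index) || peak_index < 1L)
    stop("'peak_index' must be a positive integer")
  if (length(half_width) != 1L || is.na(half_width) || half_width < 1L)
    stop("'half_width' must be a positive integer")
  if (!is.null(n_samples) &&
      (peak_index - half_width < 1L || peak_index + half_width > n_samples))
    stop("peak window extends beyond the spectrum")
  structure(list(peak_index = peak_index, half_width = half_width),
            class = "peak_region")
}

region_indices <- function(region, n_samples) {
  idx <- (region$peak_index - region$half_width):(region$peak_index + region$half_width)
  if (idx[1L] < 1L || idx[length(idx)] > n_samples)
    stop("peak window extends beyond the spectrum")
  idx
}

#' Locate the most prominent peak and its FWHM window
#'
#' Finds the global maximum of a clean spectrum (first index on ties) and
#' measures the peak's full width at half maximum by scanning outwards from
#' the maximum for the nearest half-maximum crossings on each side, with
#' linear interpolation between samples. The window half width is
#' `n = max(1, round(FWHM / 2))` in samples, clipped so the `2n + 1` window
#' stays inside the spectrum. If one side never crosses the half maximum
#' before the boundary, the distance to the boundary is used for that side.
#'
#' @param x Numeric intensity vector with a strictly positive, non-constant
#'   maximum.
#' @return A [peak_region()].
#' @export
locate_peak_region <- function(x) {
  if (!is.numeric(x) || length(x) < 3L) stop("'x' must be a numeric vector")
  m <- max(x)
  if (!is.finite(m) || m <= 0) stop("no peak: spectrum maximum must be positive")
  if (m - min(x) <= 1e-12 * abs(m)) stop("no peak: spectrum is constant")
  pk <- which.max(x)
  half <- m / 2
  left <- right <- NA_real_
  if (pk > 1L) for (i in (pk - 1L):1L) {
    if (x[i] < half) { # crossing between i and i+1
      left <- i + (half - x[i]) / (x[i + 1L] - x[i])
      break
    }
  }
  if (pk < length(x)) for (i in (pk + 1L):length(x)) {
    if (x[i] < half) {
      right <- i - (half - x[i]) / (x[i - 1L] - x[i])
      break
    }
  }
  half_left <- if (is.na(left)) pk - 1 else pk - left
  half_right <- if (is.na(right)) length(x) - pk else right - pk
  fwhm <- half_left + half_right
  n <- max(1L, as.integer(round(fwhm / 2)))
  n <- min(n, pk - 1L, length(x) - pk)
  n <- max(n, 1L)
  peak_region(pk, n, n_samples = length(x))
}

#' Simulator configuration
#'
#' Settings for [generate_dataset()]. The defaults are calibrated so that,
#' with Poisson shot noise, the global SNR of the generated pairs stays
#' inside the design band 15--145 while the peak intensity spans up to 4000
#' counts: spectra are built from 15--30 Lorentzian peaks whose heights span
#' one decade (log-uniform) and whose linewidths range from sharp
#' (chemical-like) to broad overlapping (biological-like) features.
#'
#' @param n_samples Spectrum length (default 600).
#' @param n_peaks_range Integer range for the number of Lorentzian peaks.
#' @param height_range Relative peak-height (A / Gamma) range; heights are
#'   drawn log-uniformly across it.
#' @param linewidth_range Lorentzian half-width Gamma range, in samples.
#' @param intensity_max_range Range for the clean spectrum's maximum
#'   intensity (photon counts); the lower end is the calibrated floor that
#'   keeps the SNR above ~15, the upper end is the 4000-count design maximum.
#' @param axis_from,axis_to Wavenumber axis end points.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 600L,
                       n_peaks_range = c(15L, 30L),
                       height_range = c(0.1, 1),
                       linewidth_range = c(6, 50),
                       intensity_max_range = c(190, 4000),
                       axis_from = 400, axis_to = 2000,
                       seed = 1L) {
  chk_range <- function(r, name, positive = TRUE) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1L] > r[2L])
      stop(sprintf("'%s' must be a non-empty range c(lo, hi)", name))
    if (positive && r[1L] <= 0)
      stop(sprintf("'%s' must be positive", name))
  }
  n_samples <- as.integer(n_samples)
  if (n_samples < 16L) stop("'n_samples' must be at least 16")
  chk_range(n_peaks_range, "n_peaks_range")
  chk_range(height_range, "height_range")
  chk_range(linewidth_range, "linewidth_range")
  chk_range(intensity_max_range, "intensity_max_range")
  structure(list(
    n_samples = n_samples,
    n_peaks_range = as.integer(n_peaks_range),
    height_range = as.numeric(height_range),
    linewidth_range = as.numeric(linewidth_range),
    intensity_max_range = as.numeric(intensity_max_range),
    axis_from = axis_from, axis_to = axis_to,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Draw one random clean spectrum (unscaled) on `axis`; uses the current RNG.
random_clean_spectrum <- function(config, axis) {
  step <- axis_step(axis)
  np <- sample(config$n_peaks_range[1L]:config$n_peaks_range[2L], 1L)
  lw <- stats::runif(np, config$linewidth_range[1L], config$linewidth_range[2L]) * step
  margin <- config$linewidth_range[2L] * step
  centers <- stats::runif(np, axis[1L] + margin, axis[length(axis)] - margin)
  h <- exp(stats::runif(np, log(config$height_range[1L]), log(config$height_range[2L])))
  peaks <- data.frame(amplitude = h * lw, center = centers, linewidth = lw)
  lorentzian_profile(peaks, axis)
}

#' Generate a supervised denoising dataset
#'
#' Draws `n_spectra` random clean spectra (sums of Lorentzians, scaled to a
#' random target maximum), corrupts each with Poisson shot noise, annotates
#' the most prominent peak's FWHM window on the clean spectrum, and records
#' the global SNR of the noisy realization against its reference. The result
#' is bit-reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param n_spectra Number of clean/noisy pairs to generate.
#' @return An object of class `raman_dataset`: a list with the `axis`,
#'   `clean` and `noisy` intensity matrices (one row per spectrum) and an
#'   `annotations` data.frame with columns `id`, `peak_index`, `half_width`
#'   and `snr`.
#' @export
generate_dataset <- function(config, n_spectra) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  n_spectra <- as.integer(n_spectra)
  if (n_spectra < 1L) stop("'n_spectra' must be at least 1")
  axis <- wavenumber_axis(config$n_samples, config$axis_from, config$axis_to)
  with_preserved_rng(config$seed, {
    clean <- matrix(0, n_spectra, config$n_samples)
    noisy <- matrix(0, n_spectra, config$n_samples)
    pk <- integer(n_spectra); hw <- integer(n_spectra); snr <- numeric(n_spectra)
    for (s in seq_len(n_spectra)) {
      y <- random_clean_spectrum(config, axis)
      target <- stats::runif(1L, config$intensity_max_range[1L],
                             config$intensity_max_range[2L])
      y <- scale_to_max(y, target)
      z <- as.numeric(stats::rpois(config$n_samples, y))
      reg <- locate_peak_region(y)
      clean[s, ] <- y
      noisy[s, ] <- z
      pk[s] <- reg$peak_index
      hw[s] <- reg$half_width
      snr[s] <- global_snr(z, y)
    }
    structure(list(
      axis = axis, clean = clean, noisy = noisy,
      annotations = data.frame(id = seq_len(n_spectra), peak_index = pk,
                               half_width = hw, snr = snr)
    ), class = "raman_dataset")
  })
}

#' @export
print.raman_dataset <- function(x, ...) {
  cat(sprintf("<raman_dataset> %d spectra x %d samples, global SNR %.1f-%.1f\n",
              nrow(x$clean), ncol(x$clean),
              min(x$annotations$snr), max(x$annotations$snr)))
  invisible(x)
}

# Extract pair s as a list (used by tests and evaluation helpers).
dataset_pair <- function(dataset, s) {
  list(reference = dataset$clean[s, ], noisy = dataset$noisy[s, ],
       region = peak_region(dataset$annotations$peak_index[s],
                            dataset$annotations$half_width[s],
                            ncol(dataset$clean)),
       snr = dataset$annotations$snr[s])
}
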