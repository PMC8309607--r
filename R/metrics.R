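#' Root mean square error between two spectra
#'
#' `sqrt(mean((a - b)^2))`, the noise estimate used in the SNR definitions.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have the same length")
  sqrt(mean((a - b)^2))
}

#' Global signal-to-noise ratio
#'
#' SNR of a spectrum `x` against a low-noise reference: the reference's
#' maximum intensity divided by the RMSE between `x` and the reference.
#' Returns `Inf` when `x` equals the reference exactly.
#'
#' @param x Spectrum under evaluation (noisy or denoised).
#' @param reference Noise-free (or low-noise) reference spectrum.
#' @return Positive scalar, possibly `Inf`.
#' @export
global_snr <- function(x, reference) {
  if (length(x) != length(reference)) stop("spectra must have the same length")
  m <- max(reference)
  if (!is.finite(m) || m <= 0) stop("reference maximum must be positive")
  e <- rmse(x, reference)
  if (e == 0) Inf else m / e
}

#' Peak signal-to-noise ratio
#'
#' Same ratio as [global_snr()] but with the RMSE restricted to the
#' `2n + 1` sample window around the most prominent peak. The numerator is
#' the *global* maximum of the full reference (not the window maximum), so
#' that peak and global SNR are directly comparable.
#'
#' @param x Spectrum under evaluation.
#' @param reference Reference spectrum.
#' @param region A [peak_region()] whose window lies inside both spectra.
#' @return Positive scalar, possibly `Inf`.
#' @export
peak_snr <- function(x, reference, region) {
  if (length(x) != length(reference)) stop("spectra must have the same length")
  m <- max(reference)
  if (!is.finite(m) || m <= 0) stop("reference maximum must be positive")
  idx <- region_indices(region, length(x))
  e <- rmse(x[idx], reference[idx])
  if (e == 0) Inf else m / e
}

#' SNR product of a denoiser's output
#'
#' The product of the global and peak SNR improvement ratios of `denoised`
#' over `raw`, both measured against the same `reference`:
#' `[SNR(denoised)/SNR(raw)] * [peakSNR(denoised)/peakSNR(raw)]`. Values
#' above 1 signal net improvement; a denoiser that corrupts the peak or the
#' baseline can score below 1. The identity mapping scores exactly 1.
#'
#' @param denoised Denoised spectrum.
#' @param raw Raw noisy spectrum (before denoising).
#' @param reference Noise-free reference.
#' @param region [peak_region()] for the peak term.
#' @return Positive scalar, `Inf` for a perfect denoiser.
#' @export
snr_product <- function(denoised, raw, reference, region) {
  if (length(denoised) != length(reference) || length(raw) != length(reference))
    stop("all spectra must have the same length")
  sg_raw <- global_snr(raw, reference)
  sp_raw <- peak_snr(raw, reference, region)
  if (!is.finite(sg_raw) || !is.finite(sp_raw))
    stop("raw spectrum equals the reference (infinite raw SNR); ",
         "the SNR product is undefined - evaluate against a noisy raw spectrum")
  (global_snr(denoised, reference) / sg_raw) *
    (peak_snr(denoised, reference, region) / sp_raw)
}

#' Full SNR report for one denoised spectrum
#'
#' Computes raw and denoised global SNR, raw and denoised peak SNR, and the
#' SNR product, as one data.frame row (ready to be stacked into a table).
#'
#' @inheritParams snr_product
#' @return One-row data.frame with columns `global_snr_raw`,
#'   `global_snr_denoised`, `peak_snr_raw`, `peak_snr_denoised`,
#'   `snr_product`, `peak_index`, `half_width`.
#' @export
snr_report <- function(denoised, raw, reference, region) {
  data.frame(
    global_snr_raw = global_snr(raw, reference),
    global_snr_denoised = global_snr(denoised, reference),
    peak_snr_raw = peak_snr(raw, reference, region),
    peak_snr_denoised = peak_snr(denoised, reference, region),
    snr_product = snr_product(denoised, raw, reference, region),
    peak_index = region$peak_index,
    half_width = region$half_width
  )
}

#' Write a table of SNR reports with a summary row
#'
#' Writes stacked [snr_report()] rows as a tab-separated table, appending a
#' final row holding the column means (id "mean").
#'
#' @param reports data.frame of stacked report rows.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snr_table <- function(reports, path) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1L)
  out <- cbind(id = as.character(seq_len(nrow(reports))), reports)
  means <- vapply(reports, function(col) mean(as.numeric(col)), numeric(1))
  out <- rbind(out, c(id = "mean", as.list(means)))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
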