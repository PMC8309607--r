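#' Mean square error
#'
#' `mean((predicted - target)^2)` - the standard L2 training loss for
#' denoising (no square root; the rooted form used inside the SNR metrics is
#' [rmse()]).
#'
#' @param predicted,target Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
mse <- function(predicted, target) {
  if (length(predicted) != length(target))
    stop("'predicted' and 'target' must have the same length")
  mean((predicted - target)^2)
}

#' Peak-weighted training loss
#'
#' The denoising loss: the MSE over the full spectrum plus `alpha` times the
#' MSE over the `2n + 1` sample window around the most prominent peak of the
#' *target* (clean) spectrum. `alpha = 0` reduces exactly to [mse()];
#' `alpha = 50` is the default adopted after the weighting sweep showed the
#' SNR product stops improving beyond it. The peak term is normalized by the
#' window length (set `peak_norm = "full"` to normalize by the spectrum
#' length instead).
#'
#' @param predicted Network output.
#' @param target Clean target spectrum.
#' @param region [peak_region()] computed from the target; see
#'   [locate_peak_region()].
#' @param alpha Non-negative peak weighting factor (default 50).
#' @param peak_norm Normalization of the peak term: `"window"` (by
#'   `2n + 1`, the default) or `"full"` (by the spectrum length).
#' @return Non-negative scalar.
#' @export
custom_loss <- function(predicted, target, region, alpha = 50,
                        peak_norm = c("window", "full")) {
  peak_norm <- match.arg(peak_norm)
  if (length(predicted) != length(target))
    stop("'predicted' and 'target' must have the same length")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("'alpha' must be a single non-negative number")
  idx <- region_indices(region, length(target))
  sq <- (predicted - target)^2
  denom <- if (peak_norm == "window") length(idx) else length(target)
  mean(sq) + alpha * sum(sq[idx]) / denom
}
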