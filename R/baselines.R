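#' Savitzky--Golay filter configuration
#'
#' @param window Odd window length, at least 3.
#' @param polyorder Polynomial order, non-negative and smaller than `window`.
#' @return An object of class `sg_config`.
#' @export
sg_config <- function(window, polyorder) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (is.na(window) || window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  if (is.na(polyorder) || polyorder < 0L || polyorder >= window)
    stop("'polyorder' must be non-negative and smaller than 'window'")
  structure(list(window = window, polyorder = polyorder), class = "sg_config")
}

#' Named Savitzky--Golay presets
#'
#' The two reference filters used for comparison with the network: `"SG39"`
#' (polynomial 3, window 9), which prioritizes smoothing, and `"SG57"`
#' (polynomial 5, window 7), which prioritizes peak preservation.
#'
#' @param name `"SG39"` or `"SG57"`.
#' @return An [sg_config()].
#' @export
sg_preset <- function(name) {
  presets <- list(SG39 = c(window = 9L, polyorder = 3L),
                  SG57 = c(window = 7L, polyorder = 5L))
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  sg_config(p[["window"]], p[["polyorder"]])
}

#' Savitzky--Golay smoothing
#'
#' Sliding-window least-squares polynomial smoothing: each interior sample
#' is replaced by the centre value of the degree-`polyorder` polynomial
#' fitted to its window; near the edges the polynomial fitted to the first
#' (last) full window is evaluated at the edge positions. Exactly
#' reproduces any polynomial of degree up to `polyorder`.
#'
#' @param x Numeric spectrum, at least as long as the window.
#' @param config An [sg_config()] (default the SG39 smoothing preset).
#' @return Smoothed numeric vector of the same length.
#' @export
savitzky_golay <- function(x, config = sg_preset("SG39")) {
  if (!inherits(config, "sg_config")) stop("'config' must be an sg_config")
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (length(x) < config$window)
    stop(sprintf("spectrum length %d is shorter than the window %d",
                 length(x), config$window))
  as.numeric(signal::sgolayfilt(x, p = config$polyorder, n = config$window))
}

#' Wrap a Savitzky--Golay configuration as a denoiser function
#'
#' Convenience for [evaluate_denoiser()]: returns a function mapping a
#' spectrum to its filtered version.
#'
#' @param config An [sg_config()] or preset name.
#' @return A function `numeric -> numeric`.
#' @export
sg_denoiser <- function(config) {
  if (is.character(config)) config <- sg_preset(config)
  if (!inherits(config, "sg_config")) stop("'config' must be an sg_config or preset name")
  function(x) savitzky_golay(x, config)
}
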