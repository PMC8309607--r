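#' Architecture of the 1D denoising network
#'
#' Describes the five-unit fully convolutional denoiser: every convolution
#' has stride 1 and "same" padding so each feature map keeps the input
#' width; units 1--4 are followed by batch normalization and ReLU, the final
#' unit is a linear convolution whose kernel spans the whole spectrum.
#' The default is the published structure
#' (filters, width): (256, 9), (128, 5), (64, 5), (1, 9), (1, 600).
#'
#' @param input_length Spectrum length the network accepts (default 600).
#' @param n_filters Integer vector of filters per convolutional unit.
#' @param filter_widths Integer vector of kernel widths per unit; by default
#'   the final unit's kernel spans the whole spectrum (`input_length`).
#' @param batchnorm_relu Logical vector: which units are followed by batch
#'   norm + ReLU (default all but the last).
#' @return An object of class `network_spec`: a data.frame of layers plus
#'   attributes, with input channel counts chained automatically.
#' @export
network_spec <- function(input_length = 600L,
                         n_filters = c(256L, 128L, 64L, 1L, 1L),
                         filter_widths = NULL,
                         batchnorm_relu = NULL) {
  input_length <- as.integer(input_length)
  if (is.null(filter_widths))
    filter_widths <- c(9L, 5L, 5L, 9L, input_length)
  n_filters <- as.integer(n_filters)
  filter_widths <- as.integer(filter_widths)
  nl <- length(n_filters)
  if (nl < 1L || length(filter_widths) != nl)
    stop("'n_filters' and 'filter_widths' must have the same positive length")
  if (any(n_filters < 1L) || any(filter_widths < 1L))
    stop("filter counts and widths must be positive")
  if (any(filter_widths > input_length))
    stop("filter width cannot exceed the input length")
  if (is.null(batchnorm_relu)) batchnorm_relu <- c(rep(TRUE, nl - 1L), FALSE)
  if (length(batchnorm_relu) != nl)
    stop("'batchnorm_relu' must have one entry per layer")
  layers <- data.frame(
    index = seq_len(nl),
    n_filters = n_filters,
    filter_width = filter_widths,
    in_channels = c(1L, n_filters[-nl]),
    has_batchnorm_relu = as.logical(batchnorm_relu)
  )
  structure(list(input_length = input_length, layers = layers),
            class = "network_spec")
}

#' Per-layer trainable parameter counts
#'
#' Convolution weights plus biases per unit:
#' `n_filters * filter_width * in_channels + n_filters`. Batch-norm scale
#' and shift parameters exist in the built model but are not included in
#' this count (the published per-unit counts follow the same convention).
#'
#' @param spec A [network_spec()].
#' @return Integer vector, one count per convolutional unit.
#' @export
count_parameters <- function(spec) {
  if (!inherits(spec, "network_spec")) stop("'spec' must be a network_spec")
  with(spec$layers, as.integer(n_filters * filter_width * in_channels + n_filters))
}

#' Build a denoising network with reproducible initial weights
#'
#' Initializes convolution weights He-style (normal with standard deviation
#' `sqrt(2 / (filter_width * in_channels))`, suited to the ReLU units),
#' biases at zero, batch-norm scale 1 / shift 0, and zeroed running
#' statistics. The same seed always yields the same initial model.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `raman_cnn`.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  if (!inherits(spec, "network_spec")) stop("'spec' must be a network_spec")
  layers <- with_preserved_rng(seed, lapply(seq_len(nrow(spec$layers)), function(i) {
    k <- spec$layers$filter_width[i]
    cin <- spec$layers$in_channels[i]
    cout <- spec$layers$n_filters[i]
    sd <- sqrt(2 / (k * cin))
    l <- list(
      W = array(stats::rnorm(k * cin * cout, sd = sd), dim = c(k, cin, cout)),
      b = numeric(cout),
      has_bn = spec$layers$has_batchnorm_relu[i]
    )
    if (l$has_bn) {
      l$gamma <- rep(1, cout)
      l$beta <- numeric(cout)
      l$running_mean <- numeric(cout)
      l$running_var <- rep(1, cout)
    }
    l
  }))
  structure(list(spec = spec, layers = layers, seed = as.integer(seed),
                 trained = FALSE),
            class = "raman_cnn")
}

#' @export
print.raman_cnn <- function(x, ...) {
  cat(sprintf("<raman_cnn> %d conv units, input length %d, %s\n",
              nrow(x$spec$layers), x$spec$input_length,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  counts <- count_parameters(x$spec)
  cat("  parameters/unit:", paste(counts, collapse = ", "),
      sprintf("(total %d)\n", sum(counts)))
  invisible(x)
}

as_spectra_matrix <- function(x, input_length) {
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x)) stop("spectra must be a numeric vector or matrix")
  if (ncol(x) != input_length)
    stop(sprintf("spectra have %d samples but the network expects %d",
                 ncol(x), input_length))
  x
}

#' Denoise spectra with a trained network
#'
#' Runs the forward pass in inference mode (batch norm uses the running
#' statistics accumulated during training), so repeated calls on the same
#' input give identical output. Spectra are divided by the model's
#' `input_scale` (the `intensity_scale` the network was trained with) on
#' the way in and multiplied back on the way out, so inputs and outputs
#' stay on the raw intensity scale.
#'
#' @param model A [build_network()] model, normally after [train_network()].
#' @param x A numeric vector of length `input_length`, or a matrix with one
#'   spectrum per row.
#' @return Denoised spectra in the same shape as the input.
#' @export
denoise <- function(model, x) {
  if (!inherits(model, "raman_cnn")) stop("'model' must be a raman_cnn")
  vec_in <- is.numeric(x) && is.null(dim(x))
  xm <- as_spectra_matrix(x, model$spec$input_length)
  sc <- if (is.null(model$input_scale)) 1 else model$input_scale
  out <- t(cpp_cnn_predict(model$layers, t(xm) / sc)) * sc
  if (vec_in) as.numeric(out[1L, ]) else out
}

#' Save / load a trained model
#'
#' `save_model()` writes the model as an RDS container plus a small JSON
#' sidecar recording the architecture, seed and (if present) the training
#' configuration, for provenance. `load_model()` reads the container back.
#'
#' @param model A `raman_cnn`.
#' @param path File path for the model container (`.rds`); the sidecar gets
#'   the extension `.json` appended.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "raman_cnn")) stop("'model' must be a raman_cnn")
  saveRDS(model, path)
  side <- list(
    input_length = model$spec$input_length,
    n_filters = model$spec$layers$n_filters,
    filter_widths = model$spec$layers$filter_width,
    parameters_per_unit = count_parameters(model$spec),
    init_seed = model$seed,
    input_scale = if (is.null(model$input_scale)) 1 else model$input_scale,
    trained = isTRUE(model$trained)
  )
  if (!is.null(model$train_config)) side$train_config <- unclass(model$train_config)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "raman_cnn")) stop("'", path, "' does not contain a raman_cnn model")
  model
}
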