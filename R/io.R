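#' Read a single spectrum from a two-column text file
#'
#' Expects delimited text (tab, comma or whitespace) with wavenumber in the
#' first column and intensity in the second; a single header line is
#' detected and skipped automatically.
#'
#' @param path Input file.
#' @param allow_descending If the axis is strictly decreasing, reverse both
#'   columns instead of failing.
#' @return A list with `wavenumber` and `intensity` numeric vectors.
#' @export
read_spectrum <- function(path, allow_descending = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) < 2L) stop("expected two columns (wavenumber, intensity) in ", path)
  dt <- dt[, 1:2]
  for (j in 1:2) {
    v <- suppressWarnings(as.numeric(dt[[j]]))
    bad <- which(is.na(v) & !is.na(dt[[j]]))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric value in %s, column %d, data row %d", path, j, bad[1L]))
    if (anyNA(v)) stop(sprintf("missing value in %s, column %d, data row %d",
                               path, j, which(is.na(v))[1L]))
    dt[[j]] <- v
  }
  w <- dt[[1L]]; y <- dt[[2L]]
  d <- diff(w)
  if (all(d < 0)) {
    if (!allow_descending)
      stop("wavenumber axis is descending; pass allow_descending = TRUE to reverse it")
    w <- rev(w); y <- rev(y); d <- diff(w)
  }
  if (any(d <= 0)) {
    stop(sprintf("wavenumber axis not strictly increasing at data row %d of %s",
                 which(d <= 0)[1L] + 1L, path))
  }
  list(wavenumber = w, intensity = y)
}

#' @rdname read_spectrum
#' @param wavenumber,intensity Spectrum to write.
#' @export
write_spectrum <- function(wavenumber, intensity, path) {
  if (length(wavenumber) != length(intensity))
    stop("'wavenumber' and 'intensity' must have the same length")
  data.table::fwrite(data.frame(wavenumber = wavenumber, intensity = intensity),
                     path, sep = "\t")
  invisible(path)
}

#' Write a simulated dataset as delimited text
#'
#' One matrix file per split (row = spectrum, tab-separated, no header):
#' `<prefix>_clean.tsv` and `<prefix>_noisy.tsv`, plus the annotation
#' sidecar `<prefix>_annotations.tsv` (id, peak_index, half_width, snr;
#' indices 1-based) and the axis `<prefix>_axis.tsv`.
#'
#' @param dataset A [generate_dataset()] object.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default `"dataset"`).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_dataset <- function(dataset, dir, prefix = "dataset") {
  if (!inherits(dataset, "raman_dataset")) stop("'dataset' must be a raman_dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(clean = file.path(dir, paste0(prefix, "_clean.tsv")),
             noisy = file.path(dir, paste0(prefix, "_noisy.tsv")),
             annotations = file.path(dir, paste0(prefix, "_annotations.tsv")),
             axis = file.path(dir, paste0(prefix, "_axis.tsv")))
  data.table::fwrite(data.table::as.data.table(dataset$clean), paths[["clean"]],
                     sep = "\t", col.names = FALSE)
  data.table::fwrite(data.table::as.data.table(dataset$noisy), paths[["noisy"]],
                     sep = "\t", col.names = FALSE)
  data.table::fwrite(dataset$annotations, paths[["annotations"]], sep = "\t")
  data.table::fwrite(data.frame(wavenumber = dataset$axis), paths[["axis"]], sep = "\t")
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates that the clean and noisy matrices agree in shape, that every
#' row has an annotation, and that each annotated peak window lies inside
#' the spectrum.
#'
#' @param path_clean,path_noisy Matrix files (row = spectrum).
#' @param path_annotations Annotation table (id, peak_index, half_width, snr).
#' @param path_axis Optional axis file; defaults to a unit-spaced axis.
#' @return A `raman_dataset`.
#' @export
read_dataset <- function(path_clean, path_noisy, path_annotations,
                         path_axis = NULL) {
  clean <- as.matrix(data.table::fread(path_clean, header = FALSE))
  noisy <- as.matrix(data.table::fread(path_noisy, header = FALSE))
  ann <- data.table::fread(path_annotations, header = TRUE, data.table = FALSE)
  if (!all(dim(clean) == dim(noisy)))
    stop(sprintf("clean matrix is %dx%d but noisy matrix is %dx%d",
                 nrow(clean), ncol(clean), nrow(noisy), ncol(noisy)))
  need <- c("id", "peak_index", "half_width", "snr")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  if (nrow(ann) != nrow(clean))
    stop(sprintf("%d spectra but %d annotation rows", nrow(clean), nrow(ann)))
  for (s in seq_len(nrow(ann))) {
    pk <- ann$peak_index[s]; hw <- ann$half_width[s]
    if (is.na(pk) || pk - hw < 1L || pk + hw > ncol(clean))
      stop(sprintf("annotation row %d: peak window [%d-%d, %d+%d] outside 1..%d",
                   s, pk, hw, pk, hw, ncol(clean)))
  }
  axis <- if (is.null(path_axis)) seq_len(ncol(clean)) else
    data.table::fread(path_axis, header = TRUE, data.table = FALSE)[[1L]]
  if (length(axis) != ncol(clean)) stop("axis length does not match the spectra")
  dimnames(clean) <- NULL
  dimnames(noisy) <- NULL
  structure(list(axis = as.numeric(axis), clean = clean, noisy = noisy,
                 annotations = ann[, need]),
            class = "raman_dataset")
}
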