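#' Labeled reflectance spectra
#'
#' A `spectrum_set` is the pipeline's universal currency: a numeric
#' sample-by-band reflectance matrix together with its wavelength grid,
#' a class label per sample and a unique sample id per row. Every
#' pretreatment, selector and classifier in the package consumes and/or
#' returns one.
#'
#' @param reflectance numeric matrix, samples in rows, bands in columns.
#' @param wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly ascending, one per column.
#' @param labels class identifier per sample (coerced to factor).
#' @param sample_ids unique character ids, one per sample. Defaults to
#'   `"s0001"...`.
#' @return An object of class `spectrum_set` with elements `reflectance`,
#'   `wavelengths`, `labels`, `sample_ids`.
#' @examples
#' s <- spectrum_set(matrix(runif(6), 2, 3), c(500, 600, 700), c("a", "b"))
#' n_bands(s)
#' @export
spectrum_set <- function(reflectance, wavelengths, labels,
                         sample_ids = NULL) {
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (is.null(sample_ids))
    sample_ids <- sprintf("s%04d", seq_len(nrow(reflectance)))
  labels <- as.factor(labels)
  if (length(labels) != nrow(reflectance))
    stop("invalid spectrum_set: row count != label count", call. = FALSE)
  if (length(wavelengths) != ncol(reflectance))
    stop("invalid spectrum_set: wavelength count != band count", call. = FALSE)
  if (length(wavelengths) >= 2 && any(diff(wavelengths) <= 0))
    stop("invalid spectrum_set: wavelengths must be strictly increasing",
         call. = FALSE)
  if (anyNA(reflectance) || any(!is.finite(reflectance)))
    stop("invalid spectrum_set: reflectance contains NaN/NA/Inf", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("invalid spectrum_set: duplicate sample_ids", call. = FALSE)
  if (length(sample_ids) != nrow(reflectance))
    stop("invalid spectrum_set: sample_id count != row count", call. = FALSE)
  colnames(reflectance) <- format_wavelength(wavelengths)
  rownames(reflectance) <- sample_ids
  structure(
    list(reflectance = reflectance,
         wavelengths = wavelengths,
         labels = labels,
         sample_ids = as.character(sample_ids)),
    class = "spectrum_set")
}

format_wavelength <- function(wl) sprintf("%.2f", wl)

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d samples x %d bands (%.1f-%.1f nm), %d classes\n",
              n_samples(x), n_bands(x),
              min(x$wavelengths), max(x$wavelengths),
              nlevels(x$labels)))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of samples / bands in a spectrum_set
#' @param set a `spectrum_set`.
#' @return integer count.
#' @export
n_samples <- function(set) nrow(set$reflectance)

#' @rdname n_samples
#' @export
n_bands <- function(set) ncol(set$reflectance)

#' Subset samples of a spectrum_set
#' @param x a `spectrum_set`.
#' @param i row (sample) index.
#' @param ... unused.
#' @return a `spectrum_set` with the selected samples.
#' @export
`[.spectrum_set` <- function(x, i, ...) {
  spectrum_set(x$reflectance[i, , drop = FALSE], x$wavelengths,
               droplevels(x$labels[i]), x$sample_ids[i])
}

# Replace the reflectance matrix, keeping grid/labels/ids (shape-preserving
# pretreatments use this).
set_reflectance <- function(set, mat) {
  spectrum_set(mat, set$wavelengths, set$labels, set$sample_ids)
}
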