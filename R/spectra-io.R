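#' Hyperspectral digital-number cube
#'
#' A 3-D array of raw sensor digital numbers (rows x cols x bands) with a
#' wavelength per band; the input to ROI extraction and panel-based
#' reflectance conversion.
#'
#' @param dn numeric 3-D array, `rows x cols x bands`, all values >= 0.
#' @param wavelengths numeric vector in nm, one per band.
#' @return an object of class `hypercube_image`.
#' @export
hypercube_image <- function(dn, wavelengths) {
  dn <- as.array(dn)
  if (length(dim(dn)) != 3)
    stop("invalid argument: dn must be a rows x cols x bands array",
         call. = FALSE)
  if (dim(dn)[3] != length(wavelengths))
    stop("invalid argument: band dimension != wavelength length",
         call. = FALSE)
  if (any(dn < 0)) stop("invalid argument: DN must be >= 0", call. = FALSE)
  structure(list(dn = dn, wavelengths = as.numeric(wavelengths)),
            class = "hypercube_image")
}

#' Standard-panel calibration record
#'
#' Per-band digital number and known reflectance of the standard gray
#' reference panel imaged alongside the sample.
#'
#' @param dn_panel per-band panel digital number, strictly positive.
#' @param r_panel per-band panel reflectance in (0, 1].
#' @return an object of class `panel_calibration`.
#' @export
panel_calibration <- function(dn_panel, r_panel) {
  if (length(dn_panel) != length(r_panel))
    stop("invalid argument: dn_panel and r_panel lengths differ",
         call. = FALSE)
  if (any(dn_panel <= 0))
    stop("calibration error: panel digital number must be > 0", call. = FALSE)
  if (any(r_panel <= 0 | r_panel > 1))
    stop("invalid argument: panel reflectance must be in (0, 1]",
         call. = FALSE)
  structure(list(dn_panel = as.numeric(dn_panel),
                 r_panel = as.numeric(r_panel)),
            class = "panel_calibration")
}

#' Panel-based reflectance conversion
#'
#' Converts sample digital numbers to reflectance against the gray panel:
#' `R = DN / DN_panel * R_panel`, elementwise per band. An optional dark
#' vector is subtracted from both the sample and panel DN first (dark
#' current already removed upstream is the default assumption).
#'
#' @param dn per-band sample digital numbers.
#' @param cal a [panel_calibration()].
#' @param dark optional per-band dark-current vector.
#' @return per-band reflectance vector.
#' @examples
#' cal <- panel_calibration(dn_panel = 100, r_panel = 0.5)
#' convert_reflectance(50, cal)  # 0.25
#' @export
convert_reflectance <- function(dn, cal, dark = NULL) {
  stopifnot(inherits(cal, "panel_calibration"))
  if (length(dn) != length(cal$dn_panel))
    stop("invalid argument: DN length != calibration length", call. = FALSE)
  dnn <- cal$dn_panel
  if (!is.null(dark)) {
    if (length(dark) != length(dn))
      stop("invalid argument: dark vector length mismatch", call. = FALSE)
    dn <- dn - dark
    dnn <- dnn - dark
  }
  if (any(dnn == 0))
    stop("calibration error: panel DN is zero after dark subtraction",
         call. = FALSE)
  r <- dn / dnn * cal$r_panel
  if (any(!is.finite(r)))
    stop("calibration error: non-finite reflectance produced", call. = FALSE)
  r
}

#' Average front- and back-side reflectance
#'
#' Seeds are imaged on both sides; the seed's spectrum is the elementwise
#' mean of the two.
#'
#' @param front,back reflectance vectors of equal length.
#' @return their elementwise arithmetic mean.
#' @export
average_sides <- function(front, back) {
  if (length(front) != length(back))
    stop("invalid argument: front/back lengths differ", call. = FALSE)
  (front + back) / 2
}

# Queue-based 4-connected component labeling of a logical matrix.
# Returns an integer label matrix (0 = background).
label_components_4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  queue <- integer(nr * nc)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue[1L] <- start
    lab[start] <- cur
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      r <- ((v - 1L) %% nr) + 1L
      cc <- ((v - 1L) %/% nr) + 1L
      for (nb in c(if (r > 1L) v - 1L,
                   if (r < nr) v + 1L,
                   if (cc > 1L) v - nr,
                   if (cc < nc) v + nr)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
  }
  lab
}

#' Extract the seed ROI mean spectrum from a hypercube
#'
#' Thresholds the band nearest `threshold_band`, keeps the largest
#' 4-connected component of above-threshold pixels as the seed mask, and
#' returns the per-band mean digital number over that mask.
#'
#' @param cube a [hypercube_image()].
#' @param threshold_band wavelength (nm) of the segmentation band; the
#'   nearest grid band is used. Default 685 nm, a band where seed and
#'   background contrast strongly.
#' @param threshold DN value; pixels strictly above it are foreground.
#' @return list with `mean_dn` (per-band mean over the mask) and `mask`
#'   (logical rows x cols raster).
#' @export
extract_roi_mean <- function(cube, threshold_band = 685, threshold) {
  stopifnot(inherits(cube, "hypercube_image"))
  wl <- cube$wavelengths
  if (threshold_band < min(wl) || threshold_band > max(wl))
    stop("invalid argument: threshold_band outside wavelength range",
         call. = FALSE)
  b <- which.min(abs(wl - threshold_band))
  plane <- cube$dn[, , b]
  fg <- plane > threshold
  if (!any(fg))
    stop(sprintf(
      "segmentation error: no pixel exceeds threshold %g at band %.1f nm",
      threshold, wl[b]), call. = FALSE)
  lab <- label_components_4(fg)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)  # ties: first (lowest) label wins
  mask <- lab == keep
  nb <- length(wl)
  mean_dn <- vapply(seq_len(nb), function(k) mean(cube$dn[, , k][mask]),
                    numeric(1))
  list(mean_dn = mean_dn, mask = mask)
}

#' Read / write the flat spectra-table CSV
#'
#' The table dialect is self-describing: first column `sample_id`, second
#' `label`, remaining columns named by band wavelength in nm with at least
#' two decimals; UTF-8 with a mandatory header. Reflectance round-trips to
#' at least 10 significant digits.
#'
#' @param path file path.
#' @return `read_spectra_table` returns a [spectrum_set()];
#'   `write_spectra_table` invisibly returns `path`.
#' @export
read_spectra_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (ncol(df) < 3 || names(df)[1] != "sample_id" || names(df)[2] != "label")
    stop("parse error: header must start with columns 'sample_id', 'label'",
         call. = FALSE)
  if (nrow(df) == 0)
    stop("empty-set error: spectra table has no samples", call. = FALSE)
  band_names <- names(df)[-(1:2)]
  wl <- suppressWarnings(as.numeric(band_names))
  if (anyNA(wl)) {
    bad <- band_names[which(is.na(wl))[1]]
    stop(sprintf("parse error: band column '%s' is not a numeric wavelength",
                 bad), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    dup <- df$sample_id[duplicated(df$sample_id)][1]
    stop(sprintf("parse error: duplicate sample_id '%s'", dup), call. = FALSE)
  }
  mat <- suppressWarnings(
    vapply(df[-(1:2)], as.numeric, numeric(nrow(df))))
  mat <- matrix(mat, nrow = nrow(df))
  bad <- which(is.na(mat) | is.nan(mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("parse error: non-numeric or NaN cell at row %d ('%s'), column '%s'",
                 bad[1, 1], df$sample_id[bad[1, 1]], band_names[bad[1, 2]]),
         call. = FALSE)
  }
  spectrum_set(mat, wl, df$label, df$sample_id)
}

#' @rdname read_spectra_table
#' @param set a [spectrum_set()] to write.
#' @export
write_spectra_table <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  df <- data.frame(sample_id = set$sample_ids,
                   label = as.character(set$labels),
                   stringsAsFactors = FALSE)
  mat <- format(set$reflectance, digits = 15, trim = TRUE, scientific = FALSE)
  df <- cbind(df, as.data.frame(mat, stringsAsFactors = FALSE))
  names(df) <- c("sample_id", "label", format_wavelength(set$wavelengths))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# ---- ENVI reader (read-only) -------------------------------------------

# Parse an ENVI header file into a named list. Values in { } may span lines.
parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  if (!grepl("ENVI", txt, fixed = TRUE))
    stop("parse error: not an ENVI header", call. = FALSE)
  out <- list()
  # key = { multi line value } | key = value
  pat <- "([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  starts <- m; lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    key <- tolower(trimws(sub("=.*$", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    if (startsWith(val, "{"))
      val <- trimws(gsub("[{}]", "", val))
    out[[key]] <- val
  }
  out
}

#' Read an ENVI hyperspectral cube
#'
#' Supports BIL, BIP and BSQ interleaves and data types 4 (float32) and
#' 12 (uint16), with the wavelength list taken from the header. Writing
#' cubes is out of scope.
#'
#' @param hdr_path path to the `.hdr` header file; the raw file is the
#'   header's `... .hdr` sibling (same path without the extension) unless
#'   `raw_path` is given.
#' @param raw_path optional explicit path to the binary cube.
#' @return a [hypercube_image()].
#' @export
read_envi_cube <- function(hdr_path, raw_path = NULL) {
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop(sprintf("parse error: ENVI header missing field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  ns <- as.integer(h$samples)   # columns
  nl <- as.integer(h$lines)     # rows
  nb <- as.integer(h$bands)
  dtype <- as.integer(h[["data type"]])
  interleave <- tolower(h$interleave)
  byte_order <- if (!is.null(h[["byte order"]])) as.integer(h[["byte order"]]) else 0L
  endian <- if (byte_order == 0L) "little" else "big"
  if (is.null(raw_path)) {
    raw_path <- sub("\\.hdr$", "", hdr_path, ignore.case = TRUE)
    if (!file.exists(raw_path)) {
      alt <- paste0(raw_path, c(".img", ".raw", ".dat"))
      hit <- alt[file.exists(alt)]
      if (length(hit)) raw_path <- hit[1]
    }
  }
  if (!file.exists(raw_path))
    stop(sprintf("file not found: ENVI raw data for %s", hdr_path),
         call. = FALSE)
  n_vals <- ns * nl * nb
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- switch(as.character(dtype),
    "4"  = readBin(con, "double", n = n_vals, size = 4, endian = endian),
    "12" = readBin(con, "integer", n = n_vals, size = 2, signed = FALSE,
                   endian = endian),
    stop(sprintf("parse error: unsupported ENVI data type %d (supported: 4, 12)",
                 dtype), call. = FALSE))
  if (length(vals) < n_vals)
    stop("parse error: ENVI raw file shorter than header promises",
         call. = FALSE)
  # storage orders: BSQ = [col, row, band]; BIL = [col, band, row];
  # BIP = [band, col, row]; target is [row, col, band]
  cube <- switch(interleave,
    bsq = aperm(array(vals, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(vals, c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(vals, c(nb, ns, nl)), c(3, 2, 1)),
    stop(sprintf("parse error: unsupported interleave '%s'", interleave),
         call. = FALSE))
  wl <- if (!is.null(h$wavelength))
    as.numeric(strsplit(h$wavelength, ",")[[1]])
  else seq_len(nb)
  hypercube_image(cube, wl)
}
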