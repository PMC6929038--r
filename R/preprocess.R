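# Spectral pretreatments. Each maps a spectrum_set to a spectrum_set of
# identical shape on the same wavelength grid.

# Savitzky-Golay weight matrix: S[j, ] are the weights producing the
# polynomial-fit value at band j. Interior bands use the centered window;
# edge bands refit the same-order polynomial over the truncated
# (asymmetric) window so the output keeps its shape.
sg_weight_matrix <- function(p, window_points, poly_order) {
  h <- (window_points - 1L) %/% 2L
  S <- matrix(0, p, p)
  for (j in seq_len(p)) {
    lo <- max(1L, j - h)
    hi <- min(p, j + h)
    idx <- lo:hi
    A <- outer(idx - j, 0:poly_order, "^")
    # value at window center (offset 0) = first row of the hat projector
    w <- (solve(crossprod(A), t(A)))[1L, ]
    S[j, idx] <- w
  }
  S
}

#' Savitzky-Golay smoothing
#'
#' Moving-window least-squares polynomial smoothing: each band is replaced
#' by the value at the window center of a polynomial of order `poly_order`
#' fitted over `window_points` neighboring bands. Edge bands are fitted
#' with truncated asymmetric windows of the same order, so the output has
#' the same shape as the input. The window must be odd (a centered window
#' cannot have an even point count) and larger than the polynomial order.
#'
#' @param set a [spectrum_set()].
#' @param window_points odd window length in bands (default 9).
#' @param poly_order polynomial order (default 2).
#' @return a smoothed `spectrum_set` of identical shape.
#' @export
sg_smooth <- function(set, window_points = 9L, poly_order = 2L) {
  stopifnot(inherits(set, "spectrum_set"))
  if (window_points %% 2L == 0L)
    stop(sprintf(
      "invalid argument: window_points = %d is even; a centered Savitzky-Golay window must be odd",
      window_points), call. = FALSE)
  if (window_points <= poly_order)
    stop("invalid argument: window_points must exceed poly_order",
         call. = FALSE)
  if (n_bands(set) < window_points)
    stop("invalid argument: fewer bands than window_points", call. = FALSE)
  S <- sg_weight_matrix(n_bands(set), as.integer(window_points),
                        as.integer(poly_order))
  set_reflectance(set, tcrossprod(set$reflectance, S))
}

#' First derivative of reflectance with respect to wavelength
#'
#' Interior bands use the central difference
#' `(R[x + 1] - R[x - 1]) / (lambda[x + 1] - lambda[x - 1])`; the two
#' endpoints use one-sided two-point differences so the band count is
#' preserved.
#'
#' @param set a [spectrum_set()] with at least 3 bands.
#' @return a `spectrum_set` of identical shape holding dR/dlambda
#'   (units 1/nm).
#' @export
first_derivative <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  p <- n_bands(set)
  if (p < 3) stop("invalid argument: need >= 3 bands", call. = FALSE)
  wl <- set$wavelengths
  X <- set$reflectance
  D <- matrix(0, nrow(X), p)
  D[, 2:(p - 1)] <- (X[, 3:p, drop = FALSE] - X[, 1:(p - 2), drop = FALSE]) /
    rep(wl[3:p] - wl[1:(p - 2)], each = nrow(X))
  D[, 1] <- (X[, 2] - X[, 1]) / (wl[2] - wl[1])
  D[, p] <- (X[, p] - X[, p - 1]) / (wl[p] - wl[p - 1])
  set_reflectance(set, D)
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum by its own mean and standard deviation
#' (denominator `p - 1`, with `p` the number of wavelength points), so
#' every output row has mean 0 and sd 1. Removes per-spectrum
#' multiplicative and additive scatter.
#'
#' @param set a [spectrum_set()].
#' @return the standardized `spectrum_set`.
#' @export
snv <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  X <- set$reflectance
  m <- rowMeans(X)
  s <- sqrt(rowSums((X - m)^2) / (ncol(X) - 1))
  if (any(s == 0)) {
    bad <- set$sample_ids[which(s == 0)[1]]
    stop(sprintf("degenerate-spectrum error: sample '%s' is constant", bad),
         call. = FALSE)
  }
  set_reflectance(set, (X - m) / s)
}

#' Multiplicative scatter correction
#'
#' `msc_fit` stores the reference spectrum (columnwise mean of the training
#' set). `msc_apply` regresses each spectrum `x` on the reference by
#' ordinary least squares, `x = alpha * ref + beta`, and returns the
#' corrected spectrum `(x - beta) / alpha`. Fitting on the training
#' partition only and applying to held-out data keeps the correction
#' leakage-safe; fitting on all samples reproduces the classical
#' full-data variant.
#'
#' @param train a [spectrum_set()] with >= 2 samples.
#' @return `msc_fit`: an `msc_model` with elements `reference`,
#'   and after `msc_apply`, per-sample `alpha`/`beta` are returned as
#'   attributes of the corrected set.
#' @export
msc_fit <- function(train) {
  stopifnot(inherits(train, "spectrum_set"))
  if (n_samples(train) < 2)
    stop("invalid argument: need >= 2 training spectra", call. = FALSE)
  ref <- colMeans(train$reflectance)
  if (stats::sd(ref) == 0)
    stop("degenerate-reference error: mean spectrum is constant",
         call. = FALSE)
  structure(list(reference = ref), class = "msc_model")
}

#' @rdname msc_fit
#' @param set a [spectrum_set()] to correct.
#' @param model an `msc_model` from `msc_fit`.
#' @export
msc_apply <- function(set, model) {
  stopifnot(inherits(set, "spectrum_set"), inherits(model, "msc_model"))
  ref <- model$reference
  if (n_bands(set) != length(ref))
    stop("invalid argument: band count does not match MSC reference",
         call. = FALSE)
  rc <- ref - mean(ref)
  X <- set$reflectance
  alpha <- as.vector((X - rowMeans(X)) %*% rc) / sum(rc^2)
  beta <- rowMeans(X) - alpha * mean(ref)
  if (any(alpha == 0)) {
    bad <- set$sample_ids[which(alpha == 0)[1]]
    stop(sprintf("correction error: fitted slope is zero for sample '%s'",
                 bad), call. = FALSE)
  }
  out <- set_reflectance(set, (X - beta) / alpha)
  attr(out, "alpha") <- alpha
  attr(out, "beta") <- beta
  out
}

#' FFT low-pass filtering
#'
#' Per spectrum: discrete Fourier transform over bands, brick-wall zeroing
#' of all bins whose normalized frequency (cycles per band interval,
#' Nyquist = 0.5) exceeds `cutoff`, inverse transform, real part. The
#' operation is a projection: applying it twice equals applying it once.
#'
#' @param set a [spectrum_set()].
#' @param cutoff normalized cutoff frequency in (0, 0.5] (default 0.125).
#' @return the filtered `spectrum_set`.
#' @export
fft_lowpass <- function(set, cutoff = 0.125) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!(cutoff > 0 && cutoff <= 0.5))
    stop("invalid argument: cutoff must be in (0, 0.5]", call. = FALSE)
  p <- n_bands(set)
  k <- 0:(p - 1)
  freq <- ifelse(k <= p / 2, k, k - p) / p
  keep <- abs(freq) <= cutoff + 1e-12
  Ft <- stats::mvfft(t(set$reflectance))
  Ft[!keep, ] <- 0
  set_reflectance(set, t(Re(stats::mvfft(Ft, inverse = TRUE)) / p))
}

#' Hilbert transform filter
#'
#' Removes each spectrum's mean, then applies the frequency-domain phase
#' rule of the Hilbert transform: positive-frequency components are
#' shifted by -90 degrees, negative by +90 degrees, amplitudes unchanged
#' (the Nyquist bin, whose sign is undefined, is zeroed). The output is
#' the transform itself, i.e. the imaginary part of the analytic signal
#' of the mean-removed spectrum.
#'
#' @param set a [spectrum_set()] with >= 2 bands.
#' @return the transformed `spectrum_set`.
#' @export
hilbert_filter <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  p <- n_bands(set)
  if (p < 2) stop("invalid argument: need >= 2 bands", call. = FALSE)
  k <- 0:(p - 1)
  freq <- ifelse(k <= p / 2, k, k - p) / p
  if (p %% 2L == 0L) freq[p / 2 + 1] <- 0  # Nyquist: no defined sign
  mult <- -1i * sign(freq)
  X0 <- set$reflectance - rowMeans(set$reflectance)
  Ft <- stats::mvfft(t(X0)) * mult
  set_reflectance(set, t(Re(stats::mvfft(Ft, inverse = TRUE)) / p))
}

#' Names of the available pretreatments
#' @return character vector `c("sg", "fd", "snv", "fft", "ht", "msc")`.
#' @export
pretreatment_methods <- function() c("sg", "fd", "snv", "fft", "ht", "msc")

#' Apply a pretreatment by name
#'
#' Dispatcher used by the benchmark grid. Stateless methods ignore
#' `train`; MSC fits its reference on `train` (defaulting to `set`
#' itself) so the caller controls leakage.
#'
#' @param set a [spectrum_set()] to transform.
#' @param method one of [pretreatment_methods()].
#' @param train training partition used to fit stateful pretreatments
#'   (MSC reference); default `set`.
#' @param window_points,poly_order Savitzky-Golay parameters.
#' @param cutoff FFT low-pass cutoff.
#' @return the pretreated `spectrum_set`.
#' @export
pretreat <- function(set, method, train = set,
                     window_points = 9L, poly_order = 2L, cutoff = 0.125) {
  method <- match.arg(method, pretreatment_methods())
  switch(method,
    sg  = sg_smooth(set, window_points, poly_order),
    fd  = first_derivative(set),
    snv = snv(set),
    fft = fft_lowpass(set, cutoff),
    ht  = hilbert_filter(set),
    msc = msc_apply(set, msc_fit(train)))
}
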