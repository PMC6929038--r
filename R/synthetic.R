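#' Configuration for the synthetic seed-spectra generator
#'
#' The generator emulates the statistical structure of seed reflectance
#' spectra measured by a visible/near-infrared imaging spectrometer: a
#' shared smooth reflectance template with peaks near 638 and 702 nm and a
#' valley near 675 nm, variety (class) differences confined to the
#' 638-660 nm and 700-980 nm windows, per-sample multiplicative scatter
#' (gain/offset), and additive noise that grows toward the long-wavelength
#' edge of the detector.
#'
#' @param n_classes number of varieties (default 10).
#' @param samples_per_class spectra per variety (default 120).
#' @param n_bands number of spectral bands (default 128).
#' @param wavelength_min,wavelength_max grid endpoints in nm
#'   (defaults 373 and 1043).
#' @param class_separation dimensionless scale of the between-class
#'   reflectance offsets placed inside the 638-660 and 700-980 nm windows.
#' @param scatter_gain_sd sd of the per-sample multiplicative gain
#'   (gain = 1 + Normal(0, sd)).
#' @param scatter_offset_sd sd of the per-sample additive baseline, in
#'   reflectance units.
#' @param noise_sd_base per-band additive noise sd, in reflectance units.
#' @param noise_sd_edge extra noise sd ramping linearly from 900 nm to the
#'   grid maximum (detector noise grows toward 1000 nm).
#' @param class_bump_centers optional numeric vector of bump-center
#'   wavelengths (nm) overriding the randomly placed class effects; each
#'   must lie inside one of the two class-difference windows. Used to plant
#'   known informative bands.
#' @param class_bump_amplitudes optional `n_classes x length(class_bump_centers)`
#'   matrix of bump amplitudes (before scaling by `class_separation`);
#'   defaults to standard-normal draws.
#' @param rng_seed integer seed; equal configs and seeds give bit-identical
#'   datasets.
#' @return a validated list of class `synthetic_config`.
#' @seealso [generate_dataset()]
#' @export
synthetic_config <- function(n_classes = 10L,
                             samples_per_class = 120L,
                             n_bands = 128L,
                             wavelength_min = 373,
                             wavelength_max = 1043,
                             class_separation = 0.03,
                             scatter_gain_sd = 0.05,
                             scatter_offset_sd = 0.02,
                             noise_sd_base = 0.004,
                             noise_sd_edge = 0.010,
                             class_bump_centers = NULL,
                             class_bump_amplitudes = NULL,
                             rng_seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes),
              samples_per_class = as.integer(samples_per_class),
              n_bands = as.integer(n_bands),
              wavelength_min = as.numeric(wavelength_min),
              wavelength_max = as.numeric(wavelength_max),
              class_separation = as.numeric(class_separation),
              scatter_gain_sd = as.numeric(scatter_gain_sd),
              scatter_offset_sd = as.numeric(scatter_offset_sd),
              noise_sd_base = as.numeric(noise_sd_base),
              noise_sd_edge = as.numeric(noise_sd_edge),
              class_bump_centers = if (!is.null(class_bump_centers))
                as.numeric(class_bump_centers),
              class_bump_amplitudes = if (!is.null(class_bump_amplitudes))
                as.matrix(class_bump_amplitudes),
              rng_seed = as.integer(rng_seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  assert_that(cfg$n_classes >= 1 && cfg$samples_per_class >= 1 &&
                cfg$n_bands >= 2,
              "invalid config: counts must be >= 1 (n_bands >= 2)")
  assert_that(cfg$wavelength_min < cfg$wavelength_max,
              "invalid config: wavelength_min must be < wavelength_max")
  sds <- c(cfg$class_separation, cfg$scatter_gain_sd, cfg$scatter_offset_sd,
           cfg$noise_sd_base, cfg$noise_sd_edge)
  assert_that(all(sds >= 0), "invalid config: scale parameters must be >= 0")
  if (!is.null(cfg$class_bump_amplitudes)) {
    assert_that(!is.null(cfg$class_bump_centers),
                "invalid config: amplitudes given without bump centers")
    assert_that(nrow(cfg$class_bump_amplitudes) == cfg$n_classes &&
                  ncol(cfg$class_bump_amplitudes) ==
                    length(cfg$class_bump_centers),
                "invalid config: class_bump_amplitudes must be n_classes x n_centers")
  }
  invisible(cfg)
}

#' Read a synthetic_config from a YAML key-value file
#'
#' Keys match the arguments of [synthetic_config()]; unknown keys are an
#' error. Missing keys take their defaults.
#'
#' @param path path to a YAML file.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(synthetic_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  do.call(synthetic_config, vals)
}

#' Evenly spaced wavelength grid
#'
#' @param n_bands number of bands (>= 2).
#' @param wl_min,wl_max endpoints in nm, `wl_min < wl_max`.
#' @return strictly ascending numeric vector of length `n_bands` running
#'   exactly from `wl_min` to `wl_max`.
#' @examples
#' make_wavelength_grid(3, 373, 1043)  # 373, 708, 1043
#' @export
make_wavelength_grid <- function(n_bands, wl_min, wl_max) {
  if (n_bands < 2) stop("invalid argument: n_bands must be >= 2", call. = FALSE)
  if (!(wl_min < wl_max))
    stop("invalid argument: wl_min must be < wl_max", call. = FALSE)
  seq(wl_min, wl_max, length.out = n_bands)
}

# Class-difference windows (nm). Between-class structure lives only here.
CLASS_WINDOWS <- list(c(638, 660), c(700, 980))

in_class_windows <- function(wl) {
  (wl >= CLASS_WINDOWS[[1]][1] & wl <= CLASS_WINDOWS[[1]][2]) |
    (wl >= CLASS_WINDOWS[[2]][1] & wl <= CLASS_WINDOWS[[2]][2])
}

# Shared reflectance template: a sum of Gaussian bumps chosen so the curve
# has local maxima at ~638 and ~702 nm, a local minimum at ~675 nm, and a
# broad near-infrared plateau. Amplitudes are free generator parameters.
base_template <- function(wl) {
  0.22 +
    0.16 * exp(-0.5 * ((wl - 638) / 16)^2) +
    0.20 * exp(-0.5 * ((wl - 702) / 18)^2) -
    0.10 * exp(-0.5 * ((wl - 675) / 9)^2) +
    0.30 * exp(-0.5 * ((wl - 930) / 150)^2)
}

# Smooth class effect: Gaussian bumps (sd ~ 7.5 nm -> full width ~ 15 nm)
# hard-truncated to the class-difference windows so between-class variance
# is exactly zero elsewhere.
class_effect_curves <- function(wl, n_classes, centers, amplitudes) {
  inside <- in_class_windows(wl)
  eff <- matrix(0, n_classes, length(wl))
  for (b in seq_along(centers)) {
    bump <- exp(-0.5 * ((wl - centers[b]) / 7.5)^2)
    bump[!inside] <- 0
    eff <- eff + tcrossprod(amplitudes[, b], bump)
  }
  eff
}

#' Generate a labeled synthetic spectra dataset
#'
#' Deterministic given `cfg$rng_seed`. Each sample is
#' `gain * (template + class effect) + offset + noise`, clipped to
#' `[0, 1.5]` (calibrated reflectance against a gray panel can exceed 1).
#' Labels are balanced: `samples_per_class` spectra for each of
#' `n_classes` classes named `"C01"`, `"C02"`, ...
#'
#' @param cfg a [synthetic_config()].
#' @return a [spectrum_set()] with
#'   `n_classes * samples_per_class` rows and `n_bands` columns.
#' @examples
#' set <- generate_dataset(synthetic_config(n_classes = 3,
#'                                          samples_per_class = 5,
#'                                          n_bands = 32))
#' table(set$labels)
#' @export
generate_dataset <- function(cfg) {
  validate_synthetic_config(cfg)
  wl <- make_wavelength_grid(cfg$n_bands, cfg$wavelength_min,
                             cfg$wavelength_max)
  n <- cfg$n_classes * cfg$samples_per_class
  base <- base_template(wl)
  noise_sd <- cfg$noise_sd_base + cfg$noise_sd_edge *
    pmax(0, (wl - 900) / max(cfg$wavelength_max - 900, 1))

  with_seed(cfg$rng_seed, {
    # class-effect geometry first so per-sample draws do not shift it
    if (is.null(cfg$class_bump_centers)) {
      centers <- c(runif(1, 643, 655), runif(3, 715, 965))
    } else {
      centers <- cfg$class_bump_centers
      if (!all(in_class_windows(centers)))
        stop("invalid config: class_bump_centers must lie in the 638-660 or 700-980 nm window",
             call. = FALSE)
    }
    amp <- if (is.null(cfg$class_bump_amplitudes)) {
      matrix(rnorm(cfg$n_classes * length(centers)), cfg$n_classes)
    } else cfg$class_bump_amplitudes
    eff <- cfg$class_separation *
      class_effect_curves(wl, cfg$n_classes, centers, amp)

    labels <- rep(sprintf("C%02d", seq_len(cfg$n_classes)),
                  each = cfg$samples_per_class)
    gains <- 1 + rnorm(n, 0, cfg$scatter_gain_sd)
    offsets <- rnorm(n, 0, cfg$scatter_offset_sd)
    noise <- matrix(rnorm(n * cfg$n_bands), n) *
      matrix(noise_sd, n, cfg$n_bands, byrow = TRUE)

    mean_curves <- sweep(eff, 2, base, "+")   # n_classes x p
    X <- mean_curves[rep(seq_len(cfg$n_classes),
                         each = cfg$samples_per_class), , drop = FALSE]
    X <- X * gains + offsets + noise
    X[X < 0] <- 0
    X[X > 1.5] <- 1.5
    spectrum_set(X, wl, labels)
  })
}
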