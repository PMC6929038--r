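# Fixtures and independent brute-force oracles used across test files.

# Small synthetic dataset with convenient defaults for unit tests.
tiny_set <- function(n_classes = 3, samples_per_class = 8, n_bands = 40,
                     class_separation = 0.08, scatter_gain_sd = 0.03,
                     scatter_offset_sd = 0.01, noise_sd_base = 0.002,
                     noise_sd_edge = 0.004, rng_seed = 1, ...) {
  generate_dataset(synthetic_config(
    n_classes = n_classes, samples_per_class = samples_per_class,
    n_bands = n_bands, class_separation = class_separation,
    scatter_gain_sd = scatter_gain_sd,
    scatter_offset_sd = scatter_offset_sd,
    noise_sd_base = noise_sd_base, noise_sd_edge = noise_sd_edge,
    rng_seed = rng_seed, ...))
}

# Brute-force 4-connected component labeling by iterative minimum-label
# propagation (independent of the package's flood fill).
brute_label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (!mask[r, cc]) next
      nbs <- c(if (r > 1 && mask[r - 1, cc]) lab[r - 1, cc],
               if (r < nr && mask[r + 1, cc]) lab[r + 1, cc],
               if (cc > 1 && mask[r, cc - 1]) lab[r, cc - 1],
               if (cc < nc && mask[r, cc + 1]) lab[r, cc + 1])
      m <- min(c(lab[r, cc], nbs))
      if (m < lab[r, cc]) { lab[r, cc] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  lab
}

# Direct per-window least-squares Savitzky-Golay oracle, including the
# truncated asymmetric edge windows.
sg_refit_oracle <- function(y, window_points, poly_order) {
  p <- length(y)
  h <- (window_points - 1) %/% 2
  out <- numeric(p)
  for (j in seq_len(p)) {
    idx <- max(1, j - h):min(p, j + h)
    fit <- lm(y[idx] ~ poly(idx - j, poly_order, raw = TRUE))
    out[j] <- unname(coef(fit)[1])
  }
  out
}

# Write a tiny ENVI header + raw pair; returns the header path.
write_envi_fixture <- function(dir, dn, wavelengths, interleave,
                               data_type, name = "cube") {
  nr <- dim(dn)[1]; nc <- dim(dn)[2]; nb <- dim(dn)[3]
  raw <- file.path(dir, name)
  hdr <- paste0(raw, ".hdr")
  writeLines(c(
    "ENVI",
    sprintf("samples = %d", nc),
    sprintf("lines = %d", nl <- nr),
    sprintf("bands = %d", nb),
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength = {%s}",
            paste(sprintf("%.2f", wavelengths), collapse = ", "))), hdr)
  vals <- switch(interleave,
    bsq = as.vector(aperm(dn, c(2, 1, 3))),
    bil = as.vector(aperm(dn, c(2, 3, 1))),
    bip = as.vector(aperm(dn, c(3, 2, 1))))
  con <- file(raw, "wb")
  if (data_type == 4) writeBin(as.numeric(vals), con, size = 4)
  else writeBin(as.integer(vals), con, size = 2)
  close(con)
  hdr
}

mean_centroid_distance_after_snv <- function(set) {
  z <- snv(set)$reflectance
  cents <- do.call(rbind, lapply(levels(set$labels), function(cl)
    colMeans(z[set$labels == cl, , drop = FALSE])))
  mean(dist(cents))
}

within_class_variance <- function(mat, labels) {
  mean(unlist(lapply(levels(labels), function(cl)
    apply(mat[labels == cl, , drop = FALSE], 2, var))))
}
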