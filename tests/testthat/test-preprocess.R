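# The six pretreatments: exact identities, oracle comparisons, and the
# shape-preservation contract.

make_set <- function(X, wl = seq(400, length.out = ncol(X), by = 10)) {
  spectrum_set(X, wl, rep("a", nrow(X)))
}

test_that("SG smoothing reproduces polynomials up to its order", {
  idx <- 1:30
  const <- make_set(matrix(5, 1, 30))
  expect_equal(sg_smooth(const)$reflectance, const$reflectance,
               tolerance = 1e-12)
  quad <- make_set(matrix(0.3 + 0.05 * idx - 0.002 * idx^2, 1))
  expect_equal(sg_smooth(quad, 9, 2)$reflectance, quad$reflectance,
               tolerance = 1e-10)
})

test_that("SG equals the per-window least-squares refit oracle", {
  set.seed(8)
  y <- runif(20)
  got <- sg_smooth(make_set(matrix(y, 1)), 5, 2)$reflectance[1, ]
  expect_equal(unname(got), sg_refit_oracle(y, 5, 2), tolerance = 1e-10)
})

test_that("SG interior bands agree with signal::sgolayfilt", {
  set.seed(9)
  y <- runif(40)
  got <- sg_smooth(make_set(matrix(y, 1)), 9, 2)$reflectance[1, ]
  ref <- signal::sgolayfilt(y, p = 2, n = 9)
  expect_equal(unname(got)[5:36], ref[5:36], tolerance = 1e-10)
})

test_that("SG rejects even windows with a clear error", {
  s <- tiny_set()
  expect_error(sg_smooth(s, 8, 2), "even.*odd|odd")
  expect_error(sg_smooth(s, 3, 3), "exceed")
})

test_that("first derivative: central differences over wavelength", {
  s <- spectrum_set(matrix(c(1, 2, 4), 1), c(100, 110, 120), "a")
  d <- first_derivative(s)$reflectance[1, ]
  expect_equal(unname(d), c(0.1, 0.15, 0.2))

  const <- make_set(matrix(2, 3, 10))
  expect_equal(first_derivative(const)$reflectance,
               matrix(0, 3, 10), ignore_attr = TRUE)

  wl <- seq(400, 600, by = 25)
  lin <- spectrum_set(matrix(0.001 * wl + 3, 1), wl, "a")
  expect_equal(unname(first_derivative(lin)$reflectance[1, ]),
               rep(0.001, length(wl)), tolerance = 1e-12)
})

test_that("SNV standardizes each spectrum with the p-1 denominator", {
  s <- make_set(matrix(c(1, 2, 3), 1), wl = c(1, 2, 3))
  expect_equal(unname(snv(s)$reflectance[1, ]), c(-1, 0, 1))

  r <- tiny_set(rng_seed = 4)
  z <- snv(r)$reflectance
  expect_equal(max(abs(rowMeans(z))), 0, tolerance = 1e-10)
  expect_equal(max(abs(apply(z, 1, sd) - 1)), 0, tolerance = 1e-10)

  expect_equal(snv(snv(r))$reflectance, z, tolerance = 1e-12,
               ignore_attr = TRUE)
  # affine invariance
  aff <- set_r <- r
  aff$reflectance <- 2.5 * r$reflectance + 0.3
  aff <- spectrum_set(2.5 * r$reflectance + 0.3, r$wavelengths, r$labels,
                      r$sample_ids)
  expect_equal(snv(aff)$reflectance, z, tolerance = 1e-10,
               ignore_attr = TRUE)

  flat <- spectrum_set(matrix(c(1, 1, 1, 1, 2, 3), 2, byrow = TRUE),
                       c(1, 2, 3), c("a", "b"), c("id_flat", "id_ok"))
  expect_error(snv(flat), "degenerate-spectrum.*id_flat")
})

test_that("MSC inverts affine scatter exactly and recovers a template", {
  train <- tiny_set(n_classes = 2, samples_per_class = 10, rng_seed = 6)
  model <- msc_fit(train)
  ref <- model$reference

  same <- spectrum_set(matrix(ref, 1), train$wavelengths, "a")
  out <- msc_apply(same, model)
  expect_equal(unname(out$reflectance[1, ]), unname(ref), tolerance = 1e-10)
  expect_equal(unname(attr(out, "alpha")), 1, tolerance = 1e-10)
  expect_equal(unname(attr(out, "beta")), 0, tolerance = 1e-10)

  scat <- spectrum_set(matrix(2 * ref + 3, 1), train$wavelengths, "a")
  out <- msc_apply(scat, model)
  expect_equal(unname(out$reflectance[1, ]), unname(ref), tolerance = 1e-10)
  expect_equal(unname(attr(out, "alpha")), 2, tolerance = 1e-10)
  expect_equal(unname(attr(out, "beta")), 3, tolerance = 1e-10)

  # known gains/offsets + tiny noise: corrected rows land on the template
  set.seed(11)
  template <- ref
  a_i <- runif(12, 0.7, 1.4)
  b_i <- runif(12, -0.1, 0.1)
  X <- outer(a_i, template) + b_i +
    matrix(rnorm(12 * length(template), 0, 1e-4), 12)
  noisy <- spectrum_set(X, train$wavelengths, rep("a", 12))
  corrected <- msc_apply(noisy, msc_fit(noisy))
  err <- sweep(corrected$reflectance, 2, colMeans(corrected$reflectance))
  expect_lt(max(abs(err)), 5e-3)

  flat <- spectrum_set(matrix(1, 2, 5), 1:5, c("a", "b"))
  expect_error(msc_fit(flat), "degenerate-reference")
})

test_that("FFT low-pass is a brick-wall projection with the stated cutoff", {
  p <- 80
  k <- 0:(p - 1)
  const <- make_set(matrix(3, 1, p))
  expect_equal(fft_lowpass(const)$reflectance, const$reflectance,
               tolerance = 1e-12)

  # 0.40 and 0.0625 are exact DFT bins at p = 80 (32/80 and 5/80)
  hi <- make_set(matrix(cos(2 * pi * 0.40 * k), 1, p))
  expect_lt(max(abs(fft_lowpass(hi)$reflectance)), 1e-10)

  lo <- make_set(matrix(cos(2 * pi * 0.0625 * k), 1, p))
  expect_equal(fft_lowpass(lo)$reflectance, lo$reflectance,
               tolerance = 1e-10)

  r <- tiny_set(rng_seed = 13)
  once <- fft_lowpass(r)
  expect_equal(fft_lowpass(once)$reflectance, once$reflectance,
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(fft_lowpass(r, 0), "invalid argument")
  expect_error(fft_lowpass(r, 0.7), "invalid argument")
})

test_that("Hilbert filter applies the +/-90 degree phase rule", {
  p <- 64
  k <- 0:(p - 1)
  f <- 4 / p  # exact DFT bin
  cosx <- make_set(matrix(cos(2 * pi * f * k), 1, p))
  expect_equal(unname(hilbert_filter(cosx)$reflectance[1, ]),
               sin(2 * pi * f * k), tolerance = 1e-10)

  const <- make_set(matrix(7, 1, p))
  expect_equal(max(abs(hilbert_filter(const)$reflectance)), 0,
               tolerance = 1e-12)

  # involution H(H(x)) = -x on zero-mean spectra (odd length: no Nyquist bin)
  set.seed(3)
  x <- rnorm(41)
  x <- x - mean(x)
  s <- make_set(matrix(x, 1))
  expect_equal(unname(hilbert_filter(hilbert_filter(s))$reflectance[1, ]),
               -x, tolerance = 1e-10)
})

test_that("every pretreatment preserves shape and wavelength grid", {
  s <- tiny_set(rng_seed = 21)
  for (m in pretreatment_methods()) {
    out <- pretreat(s, m)
    expect_s3_class(out, "spectrum_set")
    expect_identical(dim(out$reflectance), dim(s$reflectance))
    expect_identical(out$wavelengths, s$wavelengths)
    expect_identical(out$labels, s$labels)
  }
})

test_that("derivative after SG of a cubic equals the unsmoothed derivative", {
  # order-2 SG with a symmetric window leaves cubics unchanged at the
  # window center, so FD(SG(x)) = FD(x) wherever windows do not truncate
  wl <- seq(400, 700, length.out = 41)
  x <- 1e-7 * (wl - 550)^3 + 0.2
  s <- spectrum_set(matrix(x, 1), wl, "a")
  direct <- first_derivative(s)$reflectance[1, ]
  smoothed <- first_derivative(sg_smooth(s, 9, 2))$reflectance[1, ]
  interior <- 6:36  # full SG windows for both FD neighbors
  expect_equal(unname(smoothed[interior]), unname(direct[interior]),
               tolerance = 1e-10)
})
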