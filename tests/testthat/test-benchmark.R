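# Benchmark grid: enumeration, composition, graceful failure, confusion
# reporting and trait correlation.

test_that("grid enumeration covers the full factorial", {
  g <- grid_combinations()
  expect_equal(nrow(g), 90L)
  expect_equal(nrow(unique(g)), 90L)
  g2 <- grid_combinations(c("snv", "msc"), "pca", c("knn", "el", "svm"))
  expect_equal(nrow(g2), 6L)
  expect_error(grid_combinations(character(0)), "length")
})

test_that("a 1x1x1 grid equals running the stages manually", {
  s <- tiny_set(n_classes = 4, samples_per_class = 12, n_bands = 32,
                class_separation = 0.1, rng_seed = 14)
  seed <- 7L
  res <- run_grid(s, pretreatments = "snv", selectors = "pca",
                  classifiers = "knn", rng_seed = seed)
  entry <- res$entries[["snv|pca|knn"]]

  d <- function(off) spectrograin:::derive_seed(seed, off)
  sp <- stratified_split(s, rng_seed = d(11L))
  tr <- snv(sp$train); te <- snv(sp$test)
  m <- pca_fit(tr)
  spec <- classifier_spec(
    "knn",
    rng_seed = d(500L + spectrograin:::str_offset("snv|pca|knn")))
  pred_te <- fit_predict(spec, pca_apply(tr, m), sp$train$labels,
                         pca_apply(te, m))
  expect_equal(entry$eval$test_accuracy, mean(pred_te == sp$test$labels))

  folds <- spectrograin:::make_stratified_folds(sp$train$labels, 5, d(12L))
  hits <- 0
  for (f in 1:5) {
    trf <- snv(sp$train[folds != f]); tef <- snv(sp$train[folds == f])
    mf <- pca_fit(trf)
    p <- fit_predict(spec, pca_apply(trf, mf), trf$labels,
                     pca_apply(tef, mf))
    hits <- hits + sum(p == tef$labels)
  }
  expect_equal(entry$eval$cv_accuracy, hits / n_samples(sp$train))
})

test_that("a failing stage is recorded and the grid completes", {
  s <- tiny_set(n_classes = 3, samples_per_class = 8, n_bands = 16,
                rng_seed = 4)
  X <- s$reflectance
  X[1, ] <- 0.5  # constant spectrum: SNV must fail for it
  bad <- spectrum_set(X, s$wavelengths, s$labels, s$sample_ids)
  res <- run_grid(bad, pretreatments = c("snv", "fd"), selectors = "pca",
                  classifiers = "knn", rng_seed = 2)
  expect_equal(nrow(res$summary), 2L)
  snv_entry <- res$entries[["snv|pca|knn"]]
  expect_match(snv_entry$error, "degenerate-spectrum")
  expect_null(snv_entry$eval)
  fd_entry <- res$entries[["fd|pca|knn"]]
  expect_null(fd_entry$error)
  expect_true(is.finite(fd_entry$eval$cv_accuracy))
  expect_error(confusion_report(res, c("snv", "pca", "knn")), "lookup error")
})

test_that("grid results are deterministic and the best rule holds", {
  s <- tiny_set(n_classes = 3, samples_per_class = 10, n_bands = 24,
                class_separation = 0.1, rng_seed = 5)
  a <- run_grid(s, pretreatments = c("snv", "sg"), selectors = "pca",
                classifiers = c("knn", "bayes"), rng_seed = 6)
  b <- run_grid(s, pretreatments = c("snv", "sg"), selectors = "pca",
                classifiers = c("knn", "bayes"), rng_seed = 6)
  expect_equal(a$summary[names(a$summary) != "runtime"],
               b$summary[names(b$summary) != "runtime"])
  sm <- a$summary
  key_best <- with(a$best, paste(pretreatment, selector, classifier,
                                 sep = "|"))
  ord <- order(-sm$cv_acc, -sm$test_acc,
               paste(sm$pretreatment, sm$selector, sm$classifier, sep = "|"))
  expect_equal(key_best, with(sm[ord[1], ],
                              paste(pretreatment, selector, classifier,
                                    sep = "|")))
})

test_that("confusion report isolates a planted misassignment", {
  amp <- matrix(c(2, -2, 0,
                  -2, 2, 0,
                  0, 0, 2,
                  2, 2, -2,
                  -2, -2, -2), 5, 3, byrow = TRUE)  # well-separated classes
  s <- generate_dataset(synthetic_config(
    n_classes = 5, samples_per_class = 12, n_bands = 48,
    class_separation = 0.2, scatter_gain_sd = 0, scatter_offset_sd = 0,
    noise_sd_base = 0.001, noise_sd_edge = 0.001,
    class_bump_centers = c(650, 760, 900), class_bump_amplitudes = amp,
    rng_seed = 19))
  # two seeds drawn from class C05's distribution but labeled C04
  labels <- as.character(s$labels)
  planted <- which(labels == "C05")[1:2]
  labels[planted] <- "C04"
  mix <- spectrum_set(s$reflectance, s$wavelengths, labels, s$sample_ids)
  res <- cross_validate(classifier_spec("bayes"), mix, rng_seed = 3)
  cm <- res$confusion
  expect_equal(cm["C04", "C05"], 2L, ignore_attr = TRUE)
  off <- sum(cm) - sum(diag(cm))
  expect_equal(off, 2L)
})

test_that("confusion_report returns the matrix with per-class recalls", {
  s <- tiny_set(n_classes = 3, samples_per_class = 10, n_bands = 24,
                class_separation = 0.5, scatter_gain_sd = 0.01,
                noise_sd_base = 0.001, noise_sd_edge = 0.001, rng_seed = 22)
  res <- run_grid(s, pretreatments = "snv", selectors = "pca",
                  classifiers = "knn", rng_seed = 2)
  rep <- confusion_report(res, "snv|pca|knn")
  # CV runs inside the training partition: ceiling(0.75 * 10) = 8 per class
  expect_equal(unname(rowSums(rep$confusion)), rep(8, 3))
  expect_equal(sum(rep$confusion), 24)
  expect_length(rep$recall, 3L)
  # the best-triple list form addresses the same entry
  expect_identical(confusion_report(res, res$best)$confusion, rep$confusion)
  expect_error(confusion_report(res, "msc|pca|knn"), "lookup error")
})

test_that("trait correlation finds planted informative wavelengths", {
  trait <- c(C01 = 36.0, C02 = 42.1, C03 = 44.5, C04 = 46.5, C05 = 40.7)
  amp <- matrix((trait - mean(trait)) / sd(trait), ncol = 1)
  s <- generate_dataset(synthetic_config(
    n_classes = 5, samples_per_class = 20, n_bands = 128,
    class_separation = 0.05, scatter_gain_sd = 0.01,
    scatter_offset_sd = 0.005, noise_sd_base = 0.002, noise_sd_edge = 0.002,
    class_bump_centers = 749, class_bump_amplitudes = amp, rng_seed = 8))
  res <- correlate_trait(s, trait)
  spacing <- diff(s$wavelengths)[1]
  expect_lte(abs(res$wavelength_at_max - 749), spacing)
  expect_gt(res$max_abs_r, 0.5)

  # r = 1 when the trait IS the reflectance at a band (noise-free classes)
  clean <- generate_dataset(synthetic_config(
    n_classes = 4, samples_per_class = 5, n_bands = 64,
    class_separation = 0.2, scatter_gain_sd = 0, scatter_offset_sd = 0,
    noise_sd_base = 0, noise_sd_edge = 0, rng_seed = 3))
  j <- which.max(apply(clean$reflectance, 2, var))
  tr2 <- vapply(levels(clean$labels), function(cl)
    clean$reflectance[which(clean$labels == cl)[1], j], numeric(1))
  res2 <- correlate_trait(clean, tr2)
  expect_equal(unname(res2$correlations[j]), 1, tolerance = 1e-10)

  expect_error(correlate_trait(s, trait[1:4]), "lookup error")
  expect_error(correlate_trait(s, setNames(rep(1, 5), names(trait))),
               "degenerate-trait")
})

test_that("higher class separation never lowers the best CV accuracy", {
  mean_best <- vapply(c(0.02, 0.08, 0.25), function(sep) {
    mean(vapply(1:20, function(seed) {
      s <- tiny_set(n_classes = 3, samples_per_class = 10, n_bands = 32,
                    class_separation = sep, rng_seed = seed)
      r <- run_grid(s, pretreatments = "snv", selectors = "pca",
                    classifiers = "knn", rng_seed = seed)
      max(r$summary$cv_acc, na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_best) >= 0))
})

test_that("paper mode fits on all data and logs the leakage warning", {
  s <- tiny_set(n_classes = 3, samples_per_class = 10, n_bands = 24,
                class_separation = 0.1, rng_seed = 9)
  expect_message(
    res <- run_grid(s, pretreatments = "msc", selectors = "pca",
                    classifiers = "knn", rng_seed = 4, paper_mode = TRUE),
    "paper mode")
  e <- res$entries[[1]]
  expect_null(e$error)
  # CV in paper mode pools the full set: confusion counts all samples
  expect_equal(sum(e$eval$confusion), n_samples(s))
})

test_that("benchmark outputs are written as CSV/JSON artifacts", {
  s <- tiny_set(n_classes = 3, samples_per_class = 8, n_bands = 16,
                rng_seed = 2)
  res <- run_grid(s, pretreatments = "fd", selectors = "pca",
                  classifiers = "knn", rng_seed = 3)
  dir <- withr::local_tempdir()
  write_benchmark_result(res, dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "provenance.json")))
  expect_true(file.exists(file.path(dir, "confusion_fd_pca_knn.csv")))
  sm <- read.csv(file.path(dir, "summary.csv"))
  expect_equal(nrow(sm), 1L)
})
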