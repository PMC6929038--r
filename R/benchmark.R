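# Factorial benchmark: every pretreatment x selector x classifier
# combination evaluated on one shared stratified split with leakage-safe
# cross-validation.

#' Names of the available feature selectors
#' @return character vector `c("cars", "spa", "pca")`.
#' @export
selector_methods <- function() c("cars", "spa", "pca")

#' Enumerate the benchmark grid
#'
#' @param pretreatments,selectors,classifiers method name vectors
#'   (defaults: all six pretreatments, all three selectors, all five
#'   classifiers, i.e. the full 90-combination grid).
#' @return data.frame with one row per (pretreatment, selector,
#'   classifier) triple, in grid order.
#' @export
grid_combinations <- function(pretreatments = pretreatment_methods(),
                              selectors = selector_methods(),
                              classifiers = classifier_methods()) {
  stopifnot(length(pretreatments) > 0, length(selectors) > 0,
            length(classifiers) > 0)
  g <- expand.grid(classifier = classifiers, selector = selectors,
                   pretreatment = pretreatments,
                   stringsAsFactors = FALSE)[, 3:1]
  rownames(g) <- NULL
  g
}

# Deterministic small hash of a string; keeps derived seeds independent of
# the order methods are listed in.
str_offset <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 99991
  as.integer(h)
}

triple_key <- function(pr, sel, clf) paste(pr, sel, clf, sep = "|")

# Fit a selector on `train_set` and return the feature matrices for the
# listed spectrum_sets (train first).
fit_select <- function(selector, train_set, apply_sets, seed,
                       cars_runs, spa_m_max, k_folds) {
  if (selector == "pca") {
    model <- pca_fit(train_set)
    feats <- lapply(apply_sets, pca_apply, model = model)
    info <- list(method = "pca", n_features = model$n_retained,
                 cumulative_load = model$cumulative_load,
                 eigenvalues = model$eigenvalues)
  } else {
    res <- if (selector == "cars")
      cars_select(train_set, n_runs = cars_runs, k_folds = k_folds,
                  rng_seed = seed)
    else
      spa_select(train_set, m_max = spa_m_max, k_folds = k_folds,
                 rng_seed = seed)
    feats <- lapply(apply_sets, function(s)
      s$reflectance[, res$selected, drop = FALSE])
    info <- list(method = selector, n_features = length(res$selected),
                 selected = res$selected,
                 selected_wavelengths = res$wavelengths[res$selected],
                 rmsecv_trace = res$rmsecv_trace,
                 retained_counts = res$retained_counts,
                 best_index = res$best_index)
  }
  list(info = info, features = feats)
}

#' Run the pretreatment x selector x classifier benchmark grid
#'
#' Performs one stratified 3:1 split shared by every combination, then for
#' each triple: the pretreatment is fitted on the training partition
#' (where stateful) and applied to both partitions, the selector is fitted
#' on the pretreated training data, and the classifier is trained on the
#' selected training features. Reported per triple: training and test
#' accuracy, plus 5-fold cross-validation accuracy computed within the
#' training partition with the pretreatment and selection re-fitted on
#' each fold's training part (leakage-safe), and the pooled CV confusion
#' matrix. Any stage error is caught and recorded as a failed entry; the
#' grid always completes. Deterministic given `rng_seed`.
#'
#' With `paper_mode = TRUE` the pretreatment and selection are fitted once
#' on all samples and the 5-fold CV runs over the full set — the classical
#' full-data protocol — and a leakage warning is logged.
#'
#' @param set a [spectrum_set()].
#' @param pretreatments,selectors,classifiers non-empty method name
#'   vectors; defaults give the full 6 x 3 x 5 = 90-cell grid.
#' @param rng_seed master seed for split, folds, selection and
#'   classifiers.
#' @param k_folds CV folds (default 5).
#' @param cars_runs,spa_m_max selector budgets passed through.
#' @param paper_mode full-data fitting protocol (see above).
#' @param verbose log per-stage timings to stderr.
#' @return a `benchmark_result`: list with `entries` (one per triple:
#'   evaluation, selection summary, runtime, error), `summary`
#'   (tidy data.frame), `best` (winning triple under the
#'   cv-accuracy / test-accuracy / lexicographic tie rule) and
#'   `provenance`.
#' @export
run_grid <- function(set,
                     pretreatments = pretreatment_methods(),
                     selectors = selector_methods(),
                     classifiers = classifier_methods(),
                     rng_seed = 1L, k_folds = 5L,
                     cars_runs = 50L, spa_m_max = 30L,
                     paper_mode = FALSE, verbose = FALSE) {
  stopifnot(inherits(set, "spectrum_set"))
  pretreatments <- vapply(pretreatments, match.arg,
                          choices = pretreatment_methods(), "")
  selectors <- vapply(selectors, match.arg, choices = selector_methods(), "")
  classifiers <- vapply(classifiers, match.arg,
                        choices = classifier_methods(), "")
  grid <- grid_combinations(pretreatments, selectors, classifiers)
  log_msg <- function(...) if (verbose) message(sprintf(...))

  split_seed <- derive_seed(rng_seed, 11L)
  fold_seed <- derive_seed(rng_seed, 12L)
  sp <- stratified_split(set, rng_seed = split_seed)
  if (paper_mode) {
    message("paper mode: pretreatment/selection fitted on all samples and CV run over the full set; test information leaks into fitting")
    folds <- make_stratified_folds(set$labels, k_folds, fold_seed)
  } else {
    folds <- make_stratified_folds(sp$train$labels, k_folds, fold_seed)
  }

  # pretreatment cache: train/test (+ per-fold partitions) or an error
  pre_cache <- lapply(pretreatments, function(pr) {
    t0 <- proc.time()[3]
    out <- tryCatch({
      if (paper_mode) {
        full_p <- pretreat(set, pr, train = set)
        tr_idx <- match(sp$train$sample_ids, set$sample_ids)
        list(full = full_p, train = full_p[tr_idx], test = full_p[-tr_idx])
      } else {
        res <- list(train = pretreat(sp$train, pr, train = sp$train),
                    test = pretreat(sp$test, pr, train = sp$train))
        res$folds <- lapply(seq_len(k_folds), function(f) {
          trf <- sp$train[folds != f]
          list(train = pretreat(trf, pr, train = trf),
               test = pretreat(sp$train[folds == f], pr, train = trf))
        })
        res
      }
    }, error = function(e) structure(list(message = conditionMessage(e)),
                                     class = "grid_stage_error"))
    log_msg("pretreat %-4s %.2fs", pr, proc.time()[3] - t0)
    out
  })
  names(pre_cache) <- pretreatments

  # selection cache per (pretreatment, selector), incl. per-fold refits
  sel_cache <- list()
  for (pr in pretreatments) {
    pre <- pre_cache[[pr]]
    for (sel in selectors) {
      key <- paste(pr, sel, sep = "|")
      t0 <- proc.time()[3]
      sel_cache[[key]] <- if (inherits(pre, "grid_stage_error")) pre
      else tryCatch({
        seed <- derive_seed(rng_seed, 200L + str_offset(key))
        if (paper_mode) {
          main <- fit_select(sel, pre$full, list(pre$full), seed,
                             cars_runs, spa_m_max, k_folds)
          tr_idx <- match(sp$train$sample_ids, set$sample_ids)
          Ffull <- main$features[[1]]
          list(info = main$info,
               train = Ffull[tr_idx, , drop = FALSE],
               test = Ffull[-tr_idx, , drop = FALSE],
               cv_features = Ffull)
        } else {
          main <- fit_select(sel, pre$train, list(pre$train, pre$test),
                             seed, cars_runs, spa_m_max, k_folds)
          fold_feats <- lapply(pre$folds, function(pf) {
            fs <- fit_select(sel, pf$train, list(pf$train, pf$test),
                             seed, cars_runs, spa_m_max, k_folds)
            list(train = fs$features[[1]], test = fs$features[[2]])
          })
          list(info = main$info, train = main$features[[1]],
               test = main$features[[2]], folds = fold_feats)
        }
      }, error = function(e) structure(list(message = conditionMessage(e)),
                                       class = "grid_stage_error"))
      log_msg("select %-9s %.2fs", key, proc.time()[3] - t0)
    }
  }

  cv_labels <- if (paper_mode) set$labels else sp$train$labels
  entries <- vector("list", nrow(grid))
  names(entries) <- triple_key(grid$pretreatment, grid$selector,
                               grid$classifier)
  for (i in seq_len(nrow(grid))) {
    pr <- grid$pretreatment[i]; sel <- grid$selector[i]
    clf <- grid$classifier[i]
    key <- names(entries)[i]
    cache <- sel_cache[[paste(pr, sel, sep = "|")]]
    t0 <- proc.time()[3]
    entry <- list(pretreatment = pr, selector = sel, classifier = clf,
                  selection = NULL, eval = NULL, error = NULL)
    if (inherits(cache, "grid_stage_error")) {
      entry$error <- cache$message
    } else {
      entry$selection <- cache$info
      res <- tryCatch({
        spec <- classifier_spec(
          clf, rng_seed = derive_seed(rng_seed, 500L + str_offset(key)))
        ytr <- sp$train$labels
        pred_tr <- fit_predict(spec, cache$train, ytr, cache$train)
        pred_te <- fit_predict(spec, cache$train, ytr, cache$test)
        cvpred <- factor(rep(levels(cv_labels)[1], length(cv_labels)),
                         levels = levels(cv_labels))
        for (f in seq_len(k_folds)) {
          if (paper_mode) {
            tr <- folds != f
            cvpred[!tr] <- fit_predict(spec,
                                       cache$cv_features[tr, , drop = FALSE],
                                       cv_labels[tr],
                                       cache$cv_features[!tr, , drop = FALSE])
          } else {
            pf <- cache$folds[[f]]
            cvpred[folds == f] <- fit_predict(spec, pf$train,
                                              cv_labels[folds != f], pf$test)
          }
        }
        cm <- confusion_matrix(cv_labels, cvpred)
        list(train_accuracy = mean(pred_tr == ytr),
             test_accuracy = mean(pred_te == sp$test$labels),
             cv_accuracy = sum(diag(cm)) / sum(cm),
             confusion = cm,
             per_class_recall = diag(cm) / rowSums(cm))
      }, error = function(e) structure(list(message = conditionMessage(e)),
                                       class = "grid_stage_error"))
      if (inherits(res, "grid_stage_error")) entry$error <- res$message
      else entry$eval <- res
    }
    entry$runtime <- unname(proc.time()[3] - t0)
    entries[[i]] <- entry
    log_msg("entry %-18s %.2fs %s", key, entry$runtime,
            if (is.null(entry$error)) "" else paste("FAILED:", entry$error))
  }

  summary <- data.frame(
    pretreatment = grid$pretreatment, selector = grid$selector,
    classifier = grid$classifier,
    train_acc = vapply(entries, function(e)
      if (is.null(e$eval)) NA_real_ else e$eval$train_accuracy, 0),
    test_acc = vapply(entries, function(e)
      if (is.null(e$eval)) NA_real_ else e$eval$test_accuracy, 0),
    cv_acc = vapply(entries, function(e)
      if (is.null(e$eval)) NA_real_ else e$eval$cv_accuracy, 0),
    n_features = vapply(entries, function(e)
      if (is.null(e$selection)) NA_integer_
      else as.integer(e$selection$n_features), 0L),
    runtime = vapply(entries, function(e) e$runtime, 0),
    error = vapply(entries, function(e)
      if (is.null(e$error)) NA_character_ else e$error, ""),
    row.names = NULL, stringsAsFactors = FALSE)

  ok <- which(!is.na(summary$cv_acc))
  best <- if (length(ok)) {
    keys <- names(entries)[ok]
    o <- order(-summary$cv_acc[ok], -summary$test_acc[ok], keys)
    entries[[ok[o[1]]]][c("pretreatment", "selector", "classifier")]
  } else NULL

  structure(list(entries = entries, summary = summary, best = best,
                 provenance = list(
                   rng_seed = rng_seed, k_folds = k_folds,
                   paper_mode = paper_mode,
                   n_samples = n_samples(set), n_bands = n_bands(set),
                   package_version = as.character(
                     utils::packageVersion("spectrograin")),
                   config_hash = str_offset(paste(
                     paste(pretreatments, collapse = ","),
                     paste(selectors, collapse = ","),
                     paste(classifiers, collapse = ","),
                     rng_seed, k_folds, cars_runs, spa_m_max, paper_mode)))),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<benchmark_result> %d entries (%d failed)\n",
              nrow(s), sum(!is.na(s$error))))
  if (!is.null(x$best))
    cat(sprintf("  best: %s-%s-%s (cv %.3f)\n", x$best$pretreatment,
                x$best$selector, x$best$classifier,
                max(s$cv_acc, na.rm = TRUE)))
  invisible(x)
}

#' Confusion matrix report for one grid cell
#'
#' @param result a `benchmark_result` from [run_grid()].
#' @param triple character vector `c(pretreatment, selector, classifier)`
#'   or a single `"pre|sel|clf"` key.
#' @return list with `confusion` (rows = true classes, columns =
#'   predicted, pooled 5-fold CV counts) and `recall` (the row-normalized
#'   per-class recall table).
#' @export
confusion_report <- function(result, triple) {
  stopifnot(inherits(result, "benchmark_result"))
  key <- if (length(triple) == 3) do.call(triple_key, unname(as.list(triple)))
         else as.character(triple)
  e <- result$entries[[key]]
  if (is.null(e))
    stop(sprintf("lookup error: no grid entry '%s'", key), call. = FALSE)
  if (is.null(e$eval))
    stop(sprintf("lookup error: entry '%s' failed (%s)", key, e$error),
         call. = FALSE)
  list(confusion = e$eval$confusion, recall = e$eval$per_class_recall)
}

#' Correlate per-band reflectance with a per-class trait
#'
#' Assigns every sample its class trait value (e.g. crude protein or
#' crude fat content) and computes the Pearson correlation between trait
#' and reflectance at each band across samples.
#'
#' @param set a [spectrum_set()].
#' @param trait named numeric vector (names = class labels) or a
#'   data.frame whose first two columns are label and value. Every class
#'   in `set` must be present.
#' @return list with `correlations` (per band, named by wavelength),
#'   `max_abs_r`, `wavelength_at_max` and `band_at_max`.
#' @export
correlate_trait <- function(set, trait) {
  stopifnot(inherits(set, "spectrum_set"))
  if (is.data.frame(trait)) {
    v <- trait[[2]]
    names(v) <- as.character(trait[[1]])
    trait <- v
  }
  missing_cl <- setdiff(levels(set$labels), names(trait))
  if (length(missing_cl))
    stop(sprintf("lookup error: class '%s' missing from trait table",
                 missing_cl[1]), call. = FALSE)
  y <- unname(trait[as.character(set$labels)])
  if (stats::sd(y) == 0)
    stop("degenerate-trait error: trait has zero variance across samples",
         call. = FALSE)
  r <- suppressWarnings(as.vector(stats::cor(set$reflectance, y)))
  names(r) <- format_wavelength(set$wavelengths)
  finite <- which(is.finite(r))
  if (!length(finite))
    stop("degenerate-trait error: no band with finite correlation",
         call. = FALSE)
  b <- finite[which.max(abs(r[finite]))]
  list(correlations = r, max_abs_r = abs(r[[b]]),
       wavelength_at_max = set$wavelengths[b], band_at_max = b)
}

#' Write benchmark outputs to a directory
#'
#' Emits `summary.csv` (one row per triple), `provenance.json`, and a
#' `confusion_<pre>_<sel>_<clf>.csv` per successful entry.
#'
#' @param result a `benchmark_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_benchmark_result <- function(result, dir) {
  stopifnot(inherits(result, "benchmark_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (key in names(result$entries)) {
    e <- result$entries[[key]]
    if (is.null(e$eval)) next
    fn <- sprintf("confusion_%s_%s_%s.csv", e$pretreatment, e$selector,
                  e$classifier)
    utils::write.csv(as.data.frame.matrix(e$eval$confusion),
                     file.path(dir, fn))
  }
  invisible(dir)
}
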