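# Five classifiers behind one fit/predict contract, plus the stratified
# split and 5-fold cross-validation protocol.

classifier_defaults <- list(
  bayes = list(kernel = "gaussian"),
  svm   = list(kernel = "quadratic", box_constraint = 1,
               multiclass = "one-vs-one"),
  knn   = list(n_neighbors = 10L, distance = "euclidean", weight = "equal"),
  el    = list(ensemble_method = "subspace", n_learners = 30L,
               subspace_dim = 40L, learning_rate = 0.1),
  ann   = list(network = "backpropagation", hidden_neurons = 10L,
               max_epochs = 500L, decay = 1e-4)
)

#' Classifier specification
#'
#' Bundles a classifier name with its parameter map (defaults follow the
#' conventional settings for this kind of seed-spectra benchmark: Gaussian
#' kernel-density naive Bayes; quadratic-kernel SVM with box constraint 1
#' and one-vs-one multiclass; 10-nearest-neighbor with Euclidean distance
#' and equal weights; a random-subspace ensemble of 30 learners with
#' subspace dimension 40; a backpropagation network with 10 hidden
#' neurons) and a seed. A spec fully determines a fit. The ensemble
#' `learning_rate` is recorded for fidelity but inert under subspace
#' voting; the subspace dimension is capped at the available feature
#' count at fit time.
#'
#' @param name one of `"bayes"`, `"svm"`, `"knn"`, `"el"`, `"ann"`.
#' @param params named list overriding the defaults for `name`.
#' @param rng_seed integer seed governing subspace draws and network
#'   initialization.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, params = list(), rng_seed = 1L) {
  name <- match.arg(name, names(classifier_defaults))
  p <- utils::modifyList(classifier_defaults[[name]], params)
  num <- Filter(is.numeric, p)
  if (any(unlist(num) <= 0))
    stop("invalid argument: numeric classifier parameters must be positive",
         call. = FALSE)
  structure(list(name = name, params = p, rng_seed = as.integer(rng_seed)),
            class = "classifier_spec")
}

#' Names of the available classifiers
#' @return character vector `c("bayes", "svm", "knn", "el", "ann")`.
#' @export
classifier_methods <- function() names(classifier_defaults)

#' Stratified 3:1 train/test split
#'
#' Per class, `ceiling(3 n / 4)` samples go to the training partition and
#' the rest to the test partition (so 120 per class gives 90/30). The
#' split is deterministic given the seed.
#'
#' @param set a [spectrum_set()]; every class needs >= 4 samples.
#' @param train_fraction training fraction (default 3/4).
#' @param rng_seed integer seed.
#' @return list with `spectrum_set`s `train` and `test` (disjoint, union =
#'   input).
#' @export
stratified_split <- function(set, train_fraction = 0.75, rng_seed = 1L) {
  stopifnot(inherits(set, "spectrum_set"))
  tab <- table(set$labels)
  if (any(tab < 4)) {
    bad <- names(tab)[tab < 4][1]
    stop(sprintf("stratification error: class '%s' has only %d samples (need >= 4)",
                 bad, tab[[bad]]), call. = FALSE)
  }
  train_idx <- with_seed(rng_seed, {
    unlist(lapply(levels(set$labels), function(cl) {
      idx <- which(set$labels == cl)
      take <- ceiling(train_fraction * length(idx))
      idx[sample.int(length(idx), take)]
    }))
  })
  train_idx <- sort(train_idx)
  list(train = set[train_idx], test = set[-train_idx])
}

# ---- individual engines -------------------------------------------------

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}
standardize_apply <- function(X, st) sweep(sweep(X, 2, st$mean), 2, st$sd, "/")

# Gaussian kernel-density naive Bayes. Bandwidth per class and feature by
# the normal-reference rule 1.06 * sd * n^(-1/5) (floored to avoid
# degenerate spikes on near-constant features).
fit_bayes <- function(X, y) {
  classes <- levels(y)
  bw <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    s <- apply(Xi, 2, stats::sd)
    floor_bw <- pmax(1e-3 * pmax(apply(X, 2, stats::sd), 1e-8), 1e-9)
    pmax(1.06 * s * nrow(Xi)^(-1 / 5), floor_bw)
  })
  names(bw) <- classes
  prior <- as.vector(table(y)) / length(y)
  list(X = X, y = y, bw = bw, prior = prior, classes = classes)
}

predict_bayes <- function(fit, Xte) {
  classes <- fit$classes
  K <- length(classes)
  ll <- matrix(rep(log(fit$prior), each = nrow(Xte)), nrow(Xte), K)
  for (j in seq_len(ncol(Xte))) {
    d <- outer(Xte[, j], fit$X[, j], "-")
    for (k in seq_len(K)) {
      cols <- fit$y == classes[k]
      b <- fit$bw[[k]][j]
      dens <- rowMeans(stats::dnorm(d[, cols, drop = FALSE], sd = b))
      ll[, k] <- ll[, k] + log(pmax(dens, 1e-300))
    }
  }
  factor(classes[max.col(ll, ties.method = "first")], levels = classes)
}

# k-nearest neighbor with the documented tie rules: all neighbors tied
# with the k-th distance are included; class-vote ties are broken by the
# smallest mean neighbor distance, then by class order.
predict_knn <- function(Xtr, y, Xte, k) {
  k <- min(k, nrow(Xtr))
  classes <- levels(y)
  d2 <- outer(rowSums(Xte^2), rep(1, nrow(Xtr))) +
    outer(rep(1, nrow(Xte)), rowSums(Xtr^2)) - 2 * tcrossprod(Xte, Xtr)
  d2[d2 < 0] <- 0
  out <- character(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    di <- sqrt(d2[i, ])
    dk <- sort(di, partial = k)[k]
    nb <- which(di <= dk + 1e-12)
    votes <- table(factor(y[nb], levels = classes))
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      meand <- vapply(classes[top], function(cl)
        mean(di[nb][y[nb] == cl]), numeric(1))
      top <- top[which.min(meand)]
    }
    out[i] <- classes[top[1L]]
  }
  factor(out, levels = classes)
}

# Random-subspace ensemble of linear discriminants, majority vote; vote
# ties broken by summed posterior probability. Learners whose subspace is
# degenerate for LDA are skipped.
fit_predict_el <- function(Xtr, y, Xte, n_learners, subspace_dim, seed) {
  p <- ncol(Xtr)
  sdim <- min(subspace_dim, p)
  if (sdim < subspace_dim)
    message(sprintf("el: subspace dimension capped at %d available features",
                    sdim))
  classes <- levels(y)
  K <- length(classes)
  votes <- matrix(0L, nrow(Xte), K)
  post <- matrix(0, nrow(Xte), K)
  fitted <- 0L
  for (b in seq_len(n_learners)) {
    feats <- with_seed(derive_seed(seed, 300L + b), sample.int(p, sdim))
    # collinear bands are routine inside a random subspace; LDA's warning
    # about them is expected, not actionable
    pr <- tryCatch(suppressWarnings({
      fit <- MASS::lda(Xtr[, feats, drop = FALSE], grouping = y)
      stats::predict(fit, Xte[, feats, drop = FALSE])
    }), error = function(e) NULL)
    if (is.null(pr)) next
    fitted <- fitted + 1L
    pc <- match(as.character(pr$class), classes)
    votes[cbind(seq_len(nrow(Xte)), pc)] <- votes[cbind(seq_len(nrow(Xte)), pc)] + 1L
    post[, match(colnames(pr$posterior), classes)] <-
      post[, match(colnames(pr$posterior), classes)] + pr$posterior
  }
  if (fitted == 0L)
    stop("el error: no subspace learner could be fitted", call. = FALSE)
  out <- vapply(seq_len(nrow(Xte)), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) top <- top[which.max(post[i, top])]
    top[1L]
  }, integer(1))
  factor(classes[out], levels = classes)
}

fit_predict_ann <- function(Xtr, y, Xte, hidden, max_epochs, decay, seed) {
  classes <- levels(y)
  Ytr <- one_hot(y)
  fit <- with_seed(derive_seed(seed, 77L), {
    nnet::nnet(x = Xtr, y = Ytr, size = hidden, softmax = TRUE,
               maxit = max_epochs, decay = decay, trace = FALSE,
               MaxNWts = 100000L)
  })
  pr <- stats::predict(fit, Xte)
  factor(classes[max.col(pr, ties.method = "first")], levels = classes)
}

#' Fit a classifier and predict labels
#'
#' One contract for all five classifiers. Features are standardized using
#' training statistics for `svm`, `knn` and `ann`; `bayes` and `el`
#' operate on raw features. Deterministic given the spec's seed (which
#' governs subspace draws and network initialization).
#'
#' @param spec a [classifier_spec()].
#' @param train_x,train_y training features (matrix) and labels.
#' @param test_x test features with the same column count.
#' @return factor of predicted labels, levels = training class levels.
#' @export
fit_predict <- function(spec, train_x, train_y, test_x) {
  stopifnot(inherits(spec, "classifier_spec"))
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- droplevels(as.factor(train_y))
  if (nlevels(train_y) < 2)
    stop("invalid argument: training data must contain >= 2 classes",
         call. = FALSE)
  if (ncol(test_x) != ncol(train_x))
    stop("invalid argument: test feature count differs from training",
         call. = FALSE)
  p <- spec$params
  if (spec$name %in% c("svm", "knn", "ann")) {
    st <- standardize_fit(train_x)
    train_x <- standardize_apply(train_x, st)
    test_x <- standardize_apply(test_x, st)
  }
  switch(spec$name,
    bayes = predict_bayes(fit_bayes(train_x, train_y), test_x),
    svm = {
      fit <- e1071::svm(train_x, train_y, kernel = "polynomial", degree = 2,
                        coef0 = 1, gamma = 1 / ncol(train_x),
                        cost = p$box_constraint, scale = FALSE)
      stats::predict(fit, test_x)
    },
    knn = predict_knn(train_x, train_y, test_x, p$n_neighbors),
    el = fit_predict_el(train_x, train_y, test_x, p$n_learners,
                        p$subspace_dim, spec$rng_seed),
    ann = fit_predict_ann(train_x, train_y, test_x, p$hidden_neurons,
                          p$max_epochs, p$decay, spec$rng_seed))
}

# Confusion matrix (rows = truth, cols = predicted) over shared levels.
confusion_matrix <- function(truth, pred) {
  lv <- levels(as.factor(truth))
  table(truth = factor(truth, levels = lv),
        predicted = factor(pred, levels = lv))
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Each sample is predicted exactly once by a model not trained on it;
#' the pooled out-of-fold predictions give the CV accuracy (trace over
#' total) and the class-by-class confusion matrix.
#'
#' @param spec a [classifier_spec()].
#' @param set a [spectrum_set()] (its reflectance matrix is the feature
#'   matrix); every class needs >= k samples.
#' @param k number of folds (default 5).
#' @param rng_seed fold-assignment seed.
#' @return list with `cv_accuracy`, `confusion` and `per_class_recall`.
#' @export
cross_validate <- function(spec, set, k = 5L, rng_seed = 1L) {
  stopifnot(inherits(set, "spectrum_set"))
  cv_xy(spec, set$reflectance, set$labels, k, rng_seed)
}

# CV on a plain feature matrix; also used by the benchmark on selected
# feature matrices.
cv_xy <- function(spec, X, labels, k = 5L, rng_seed = 1L) {
  labels <- as.factor(labels)
  folds <- make_stratified_folds(labels, k, rng_seed)
  pred <- factor(rep(levels(labels)[1], length(labels)),
                 levels = levels(labels))
  for (f in seq_len(k)) {
    tr <- folds != f
    pred[!tr] <- fit_predict(spec, X[tr, , drop = FALSE], labels[tr],
                             X[!tr, , drop = FALSE])
  }
  cm <- confusion_matrix(labels, pred)
  list(cv_accuracy = sum(diag(cm)) / sum(cm),
       confusion = cm,
       per_class_recall = diag(cm) / rowSums(cm))
}
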