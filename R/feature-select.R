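# Wavelength / feature extraction: CARS, SPA and Kaiser-rule PCA.

new_selection_result <- function(method, selected, wavelengths, rmsecv_trace,
                                 best_index, retained_counts = NULL,
                                 params = list()) {
  structure(list(method = method,
                 selected = as.integer(selected),
                 wavelengths = wavelengths,
                 rmsecv_trace = rmsecv_trace,
                 retained_counts = retained_counts,
                 best_index = as.integer(best_index),
                 params = params),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %s> %d bands selected (best at trace index %d)\n",
              x$method, length(x$selected), x$best_index))
  cat("  wavelengths (nm):",
      paste(sprintf("%.0f", x$wavelengths[x$selected]), collapse = ", "), "\n")
  invisible(x)
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Iterative selection alternating an enforced exponentially decreasing
#' retention schedule (EDF) with adaptive reweighted sampling by PLS
#' regression-coefficient magnitude. Each sampling run draws a stratified
#' calibration subset, fits a PLS-DA model on the currently retained
#' bands, keeps the top bands by coefficient magnitude down to the EDF
#' count `r(i) * p` (with `r(1) = 1` and `r(n_runs) = 2/p`), resamples
#' that set with probability proportional to coefficient magnitude
#' (without replacement, at the same count), and records the retained
#' set's RMSECV on the full data. The retained set of the
#' minimum-RMSECV run is returned (first minimum under ties).
#'
#' @param set a [spectrum_set()].
#' @param n_runs number of sampling runs (default 50).
#' @param calib_fraction fraction of samples in each calibration subset.
#' @param n_components PLS latent variables; `NULL` picks the inner-CV
#'   RMSECV minimizer over 1..10 on the full band set, reused across runs.
#' @param k_folds folds for RMSECV.
#' @param rng_seed seed; the whole procedure is deterministic given it.
#' @return a `selection_result` with fields `selected` (ascending band
#'   indices), `rmsecv_trace`, `retained_counts` and `best_index`.
#' @export
cars_select <- function(set, n_runs = 50L, calib_fraction = 0.8,
                        n_components = NULL, k_folds = 5L, rng_seed = 1L) {
  stopifnot(inherits(set, "spectrum_set"))
  p <- n_bands(set)
  if (p < 2 || n_runs < 2)
    stop("invalid argument: need >= 2 bands and >= 2 runs", call. = FALSE)
  X <- set$reflectance
  labels <- set$labels
  fold_seed <- derive_seed(rng_seed, 999L)  # same folds for every run's RMSECV
  if (is.null(n_components))
    n_components <- choose_pls_ncomp(X, labels, k_folds,
                                     derive_seed(rng_seed, 7L))
  # EDF schedule: r(i) = a * exp(-k i), r(1) = 1, r(n_runs) = 2/p
  kk <- log(p / 2) / (n_runs - 1)
  aa <- exp(kk)
  sched <- pmax(2L, as.integer(round(aa * exp(-kk * seq_len(n_runs)) * p)))
  Y <- one_hot(labels)
  retained <- seq_len(p)
  trace <- numeric(n_runs)
  counts <- integer(n_runs)
  sets <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    calib <- stratified_sample_idx(labels, calib_fraction,
                                   derive_seed(rng_seed, i))
    ncomp_i <- min(n_components, length(retained))
    fit <- pls_fit(X[calib, retained, drop = FALSE],
                   Y[calib, , drop = FALSE], ncomp_i)
    mag <- sqrt(rowSums(fit$coefficients^2))
    keep_n <- sched[i]
    if (keep_n < 2L || length(retained) < 2L)
      stop("internal error: CARS retention schedule violated", call. = FALSE)
    keep_n <- min(keep_n, length(retained))
    ord <- order(-mag, seq_along(mag))       # ties: first (lowest) index
    edf_set <- retained[ord[seq_len(keep_n)]]
    edf_mag <- mag[ord[seq_len(keep_n)]]
    # adaptive reweighted sampling, without replacement, to the same count
    retained <- with_seed(derive_seed(rng_seed, 100000L + i), {
      if (all(edf_mag > 0))
        sort(sample(edf_set, keep_n, prob = edf_mag))
      else sort(edf_set)
    })
    counts[i] <- length(retained)
    sets[[i]] <- retained
    trace[i] <- pls_rmsecv(X[, retained, drop = FALSE], labels,
                           min(n_components, length(retained)),
                           k_folds, fold_seed)$rmsecv
  }
  best <- which.min(trace)                  # first minimum under ties
  new_selection_result("cars", sets[[best]], set$wavelengths, trace, best,
                       retained_counts = counts,
                       params = list(n_runs = n_runs,
                                     calib_fraction = calib_fraction,
                                     n_components = n_components,
                                     k_folds = k_folds,
                                     rng_seed = rng_seed))
}

# Build one successive-projections chain from a starting column. `Xc` is
# the column-centered matrix; returns the ordered chain (possibly shorter
# than m_max if the residual space is exhausted).
spa_chain <- function(Xc, start, m_max, tol = 1e-12) {
  p <- ncol(Xc)
  chain <- integer(m_max)
  R <- Xc
  chosen <- logical(p)
  nrm <- sqrt(sum(R[, start]^2))
  if (nrm < tol) return(integer(0))
  chain[1] <- start; chosen[start] <- TRUE
  q <- R[, start] / nrm
  R <- R - tcrossprod(q, as.vector(crossprod(R, q)))
  for (m in seq_len(m_max - 1L)) {
    norms2 <- colSums(R^2)
    norms2[chosen] <- -1
    j <- which.max(norms2)
    if (norms2[j] < tol) return(chain[seq_len(m)])   # truncated chain
    chain[m + 1L] <- j; chosen[j] <- TRUE
    q <- R[, j] / sqrt(norms2[j])
    R <- R - tcrossprod(q, as.vector(crossprod(R, q)))
  }
  chain
}

# Incremental Gram-Schmidt CV evaluation: squared test error of the
# least-squares fit of Ytr on every prefix of the (intercept-first) column
# chain. Returns a vector of summed squared errors per band-prefix size.
gs_prefix_sqerr <- function(Atr, Ytr, Ate, Yte, tol = 1e-10) {
  m <- ncol(Atr)
  n <- nrow(Atr)
  Q <- matrix(0, n, m)
  Qte <- matrix(0, nrow(Ate), m)
  Rup <- matrix(0, m, m)
  pred <- matrix(0, nrow(Ate), ncol(Yte))
  out <- rep(NA_real_, m - 1L)
  for (j in seq_len(m)) {
    v <- Atr[, j]; vte <- Ate[, j]
    if (j > 1L) {
      r <- crossprod(Q[, 1:(j - 1L), drop = FALSE], v)
      Rup[1:(j - 1L), j] <- r
      v <- v - Q[, 1:(j - 1L), drop = FALSE] %*% r
      vte <- vte - Qte[, 1:(j - 1L), drop = FALSE] %*% r
    }
    nj <- sqrt(sum(v^2))
    if (nj < tol) break                       # rank-deficient prefix
    Rup[j, j] <- nj
    Q[, j] <- v / nj
    Qte[, j] <- vte / nj
    pred <- pred + outer(Qte[, j], as.vector(crossprod(Q[, j], Ytr)))
    if (j > 1L) out[j - 1L] <- sum((pred - Yte)^2)
  }
  out
}

#' Successive projections algorithm (SPA) band selection
#'
#' For every candidate starting band a chain of up to `m_max` bands is
#' grown by successive projections: each next band maximizes the norm of
#' its column's projection onto the orthogonal complement of the bands
#' already chosen (duplicated or collinear bands therefore have zero
#' projection and can never be co-selected). Each chain prefix is scored
#' by the RMSE of a least-squares fit of the one-hot class indicator
#' under stratified 5-fold CV, and the winner is the smallest prefix size
#' whose RMSE is within `plateau_tol` times the global minimum (RMSE
#' flattens once the informative bands are in; the plateau rule picks the
#' knee).
#'
#' @param set a [spectrum_set()].
#' @param m_max maximum chain length (default 30, capped at
#'   `min(bands, samples - 2)`).
#' @param k_folds CV folds for the RMSE evaluation.
#' @param plateau_tol plateau tolerance relative to the global minimum
#'   RMSE (default 1.01).
#' @param rng_seed seed controlling the fold assignment.
#' @return a `selection_result`; `rmsecv_trace` holds the winning chain's
#'   RMSE per prefix size and `best_index` the selected size.
#' @export
spa_select <- function(set, m_max = 30L, k_folds = 5L, plateau_tol = 1.01,
                       rng_seed = 1L) {
  stopifnot(inherits(set, "spectrum_set"))
  p <- n_bands(set)
  n <- n_samples(set)
  m_max <- min(m_max, p, n - 2L)
  if (m_max < 1) stop("invalid argument: m_max must be >= 1", call. = FALSE)
  X <- set$reflectance
  Xc <- sweep(X, 2, colMeans(X))
  Y <- one_hot(set$labels)
  folds <- make_stratified_folds(set$labels, k_folds,
                                 derive_seed(rng_seed, 5L))
  chains <- lapply(seq_len(p), function(s) spa_chain(Xc, s, m_max))
  # RMSE[chain, m] pooled over folds
  rmse <- matrix(NA_real_, p, m_max)
  nK <- n * ncol(Y)
  for (s in seq_len(p)) {
    ch <- chains[[s]]
    if (length(ch) < 1) next
    sq <- rep(0, length(ch))
    ok <- rep(TRUE, length(ch))
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      A <- cbind(1, X[, ch, drop = FALSE])
      e <- gs_prefix_sqerr(A[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                           A[!tr, , drop = FALSE], Y[!tr, , drop = FALSE])
      ok <- ok & !is.na(e)
      e[is.na(e)] <- 0
      sq <- sq + e
    }
    vals <- sqrt(sq / nK)
    vals[!ok] <- NA_real_
    rmse[s, seq_along(ch)] <- vals
  }
  if (all(is.na(rmse)))
    stop("SPA error: no evaluable chain", call. = FALSE)
  gmin <- min(rmse, na.rm = TRUE)
  thresh <- plateau_tol * gmin
  sel_m <- NA_integer_
  for (m in seq_len(m_max)) {
    if (any(!is.na(rmse[, m]) & rmse[, m] <= thresh)) { sel_m <- m; break }
  }
  col <- rmse[, sel_m]
  sel_chain <- which.min(replace(col, is.na(col), Inf))  # first tie wins
  selected <- sort(chains[[sel_chain]][seq_len(sel_m)])
  new_selection_result("spa", selected, set$wavelengths,
                       rmsecv_trace = rmse[sel_chain, ],
                       best_index = sel_m,
                       params = list(m_max = m_max, k_folds = k_folds,
                                     plateau_tol = plateau_tol,
                                     rng_seed = rng_seed,
                                     start_band = sel_chain))
}

#' Kaiser-rule principal component model
#'
#' `pca_fit` standardizes each band (mean 0, sd 1 from the training data),
#' eigendecomposes the correlation matrix, and retains the components with
#' eigenvalue greater than 1 (a component with eigenvalue below 1 carries
#' less variance than a single original standardized band); at least one
#' component is always kept. Zero-variance bands are dropped with a
#' warning and recorded in the model. `pca_apply` standardizes new spectra
#' with the stored statistics and projects onto the retained loadings.
#'
#' @param train a [spectrum_set()] with >= 2 samples.
#' @return `pca_fit`: a `pc_model` with `loadings` (band x component,
#'   orthonormal columns), `eigenvalues` (all, non-increasing),
#'   `n_retained`, `column_means`, `column_sds`, `kept_bands`,
#'   `cumulative_load` (fraction of total variance in the retained
#'   components).
#' @export
pca_fit <- function(train) {
  stopifnot(inherits(train, "spectrum_set"))
  if (n_samples(train) < 2)
    stop("invalid argument: need >= 2 training samples", call. = FALSE)
  X <- train$reflectance
  sds <- unname(apply(X, 2, stats::sd))
  kept <- which(sds > 0)
  if (length(kept) < length(sds))
    warning(sprintf("dropping %d zero-variance band(s) before PCA",
                    length(sds) - length(kept)))
  X <- X[, kept, drop = FALSE]
  mu <- colMeans(X)
  sdv <- sds[kept]
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  n <- nrow(Z); p <- ncol(Z)
  sv <- svd(Z)
  ev <- rep(0, p)
  ev[seq_along(sv$d)] <- sv$d^2 / (n - 1)
  n_retained <- max(1L, sum(ev > 1))
  structure(list(loadings = sv$v[, seq_len(n_retained), drop = FALSE],
                 eigenvalues = ev,
                 n_retained = n_retained,
                 column_means = mu,
                 column_sds = sdv,
                 kept_bands = kept,
                 n_bands_in = length(sds),
                 cumulative_load = sum(ev[seq_len(n_retained)]) / p),
            class = "pc_model")
}

#' @rdname pca_fit
#' @param set a [spectrum_set()] to project.
#' @param model a `pc_model` from `pca_fit`.
#' @return `pca_apply`: an `n x n_retained` score matrix.
#' @export
pca_apply <- function(set, model) {
  stopifnot(inherits(set, "spectrum_set"), inherits(model, "pc_model"))
  if (n_bands(set) != model$n_bands_in)
    stop("invalid argument: band count does not match the fitted PCA",
         call. = FALSE)
  X <- set$reflectance[, model$kept_bands, drop = FALSE]
  Z <- sweep(sweep(X, 2, model$column_means), 2, model$column_sds, "/")
  Z %*% model$loadings
}
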