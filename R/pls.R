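# Partial-least-squares engine. Class labels are one-hot coded and
# the indicator matrix regressed on the (column-centered) spectra; this is
# the regression engine that CARS presupposes and the basis of the RMSECV
# selection criterion.

# Fit a PLS2 regression of Y (n x K) on X (n x p) with `ncomp` latent
# variables. Each component is the NIPALS fixed point, computed exactly as
# the dominant singular pair of the deflated cross-covariance X'Y (the
# K x K eigenproblem is solved directly instead of iterating, which is
# what the NIPALS inner loop converges to); X is deflated after each
# component. Returns the p x K coefficient matrix for centered data plus
# the centering constants. Extraction stops early if the residual has no
# covariance left.
pls_fit <- function(X, Y, ncomp, tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); K <- ncol(Y)
  ncomp <- min(ncomp, p, n - 1L)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  E <- sweep(X, 2, x_mean); F <- sweep(Y, 2, y_mean)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- matrix(0, K, ncomp)
  a <- 0L
  for (comp in seq_len(ncomp)) {
    A <- crossprod(E, F)                 # p x K cross-covariance
    M <- crossprod(A)                    # K x K
    if (sum(diag(M)) < tol) break
    q0 <- eigen(M, symmetric = TRUE)$vectors[, 1]
    if (q0[which.max(abs(q0))] < 0) q0 <- -q0   # fix sign (predictions invariant)
    w <- as.vector(A %*% q0)
    wn <- sqrt(sum(w^2))
    if (wn < tol) break
    w <- w / wn
    tt <- as.vector(E %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < tol) break
    q <- crossprod(F, tt) / tt2
    pv <- crossprod(E, tt) / tt2
    E <- E - tcrossprod(tt, pv)
    F <- F - tcrossprod(tt, q)
    a <- comp
    W[, a] <- w; P[, a] <- pv; Q[, a] <- q
  }
  if (a == 0L) stop("PLS error: no latent component could be extracted",
                    call. = FALSE)
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Q <- Q[, seq_len(a), drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(Q))
  list(coefficients = B, x_mean = x_mean, y_mean = y_mean,
       n_components = a)
}

pls_predict <- function(fit, X) {
  sweep(sweep(as.matrix(X), 2, fit$x_mean) %*% fit$coefficients,
        2, fit$y_mean, "+")
}

#' PLS-DA cross-validated error and band coefficients
#'
#' One-hot encodes the class labels, fits a PLS2 regression of the
#' indicator matrix on the spectra, and reports the root mean square error
#' of cross-validation (RMSECV) under stratified k-fold CV, pooled over
#' all indicator columns and samples. Also returns per-band coefficient
#' magnitudes (row-wise Euclidean norm of the band x class coefficient
#' matrix from a full-data fit), the weights that drive CARS.
#'
#' @param X numeric sample x band matrix.
#' @param labels class per sample (>= 2 classes).
#' @param n_components number of PLS latent variables.
#' @param k_folds folds for cross-validation (default 5, stratified).
#' @param rng_seed seed controlling the fold assignment.
#' @return list with `rmsecv` (scalar), `coef_magnitude` (per band) and
#'   `n_components`.
#' @export
pls_rmsecv <- function(X, labels, n_components, k_folds = 5L, rng_seed = 1L) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2)
    stop("invalid argument: need >= 2 classes", call. = FALSE)
  n <- nrow(X)
  max_comp <- min(n - ceiling(n / k_folds) - 1L, ncol(X))
  if (n_components > max_comp)
    stop(sprintf(
      "invalid argument: n_components = %d exceeds the limit %d for %d samples x %d bands under %d-fold CV",
      n_components, max_comp, n, ncol(X), k_folds), call. = FALSE)
  Y <- one_hot(labels)
  folds <- make_stratified_folds(labels, k_folds, rng_seed)
  sq <- 0
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    fit <- pls_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], n_components)
    pred <- pls_predict(fit, X[!tr, , drop = FALSE])
    sq <- sq + sum((pred - Y[!tr, , drop = FALSE])^2)
  }
  full <- pls_fit(X, Y, n_components)
  list(rmsecv = sqrt(sq / (n * ncol(Y))),
       coef_magnitude = sqrt(rowSums(full$coefficients^2)),
       n_components = full$n_components)
}

# Pick the PLS component count by inner CV: argmin RMSECV over 1..max_try.
choose_pls_ncomp <- function(X, labels, k_folds, rng_seed, max_try = 10L) {
  n <- nrow(X)
  limit <- min(max_try, n - ceiling(n / k_folds) - 1L, ncol(X))
  errs <- vapply(seq_len(limit), function(a)
    pls_rmsecv(X, labels, a, k_folds, rng_seed)$rmsecv, numeric(1))
  which.min(errs)  # first minimum under ties
}
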