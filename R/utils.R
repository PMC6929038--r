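# Internal helpers shared across modules: seeded evaluation, stratified
# sampling/folds, one-hot coding.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic child seed; stays well below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1000003L) * 1009 + offset) %% 2147483647L
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin across folds. Every class must have >= k members so that no
# fold misses a class.
make_stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    bad <- names(tab)[tab < k][1L]
    stop(sprintf(
      "stratification error: class '%s' has %d samples, fewer than k = %d folds",
      bad, tab[[bad]], k), call. = FALSE)
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Stratified subsample of round(fraction * n_c) per class, without replacement.
stratified_sample_idx <- function(labels, fraction, seed) {
  labels <- as.factor(labels)
  with_seed(seed, {
    out <- lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      take <- max(1L, round(fraction * length(idx)))
      idx[sample.int(length(idx), take)]
    })
    sort(unlist(out))
  })
}

# One-hot indicator matrix (n x K), columns in factor-level order.
one_hot <- function(labels) {
  labels <- as.factor(labels)
  Y <- matrix(0, length(labels), nlevels(labels),
              dimnames = list(NULL, levels(labels)))
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}
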