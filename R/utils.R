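# Internal helpers shared across modules.

#' @noRd
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_int <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stopf("`%s` must be a single integer >= %s", name, min)
  as.integer(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# stream; `seed = NULL` leaves the ambient stream in charge.
#' @noRd
with_seed_or_stream <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Stratified index split: one seeded 50:50 holdout per class. Returns a
# logical vector marking the training half.
#' @noRd
stratified_holdout <- function(labels) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- ceiling(length(idx) / 2)
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

# Stratified k-fold assignment (1..k per sample).
#' @noRd
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
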