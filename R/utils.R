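# internal helpers

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Stratified assignment of samples to k folds. Within each class the
# (shuffled) members are dealt round-robin, so fold sizes differ by at most
# one per class. Uses the current RNG stream.
stratified_folds <- function(labels, k) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop(sprintf("class '%s' has %d samples, fewer than k = %d folds",
                   cl, length(idx), k))
    }
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(sprintf(...), call. = FALSE)
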