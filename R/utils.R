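# Internal helpers shared across modules: seeded RNG scoping, child-seed
# derivation, stratified fold assignment, and a fast tie-corrected AUC.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seed from a master seed and a stream name, kept inside
# 32-bit integer range. Distinct names give distinct, reproducible streams.
child_seed <- function(master, name, index = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master) * 7919 + h * 104729 + index * 15485863) %%
               2147483647)
}

# Stratified k-fold assignment: within each class, patients are shuffled and
# dealt round-robin so every fold keeps both classes where counts allow.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Tie-corrected Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(tie).
auc_mw <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires both classes to be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
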