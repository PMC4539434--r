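# evaluate expr with a local RNG seed, leaving the caller's RNG state alone
with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}

# stratified k-fold assignment: within each level of `strata`, samples are
# spread over folds as evenly as possible; returns integer fold ids
stratified_folds <- function(strata, k, seed) {
  strata <- as.character(strata)
  fold_id <- integer(length(strata))
  with_seed(seed, {
    for (g in unique(strata)) {
      idx <- which(strata == g)
      if (length(idx) < k)
        stop("group '", g, "' has fewer samples (", length(idx),
             ") than folds (", k, ")")
      fold_id[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  fold_id
}
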