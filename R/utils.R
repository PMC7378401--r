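# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so library code never
# clobbers user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-stage seed derivation from a master seed.  Stage
# offsets are spaced so per-resample schedules (seed + b) never collide;
# result is kept inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 1e4L, features = 2e4L, decode = 3e4L,
               stability = 4e4L, report = 5e4L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max)
}

# Stratified fold assignment: shuffles within each class then deals folds
# round-robin, so every fold holds both classes whenever n_class >= folds.
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

`%||%` <- function(a, b) if (is.null(a)) b else a
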