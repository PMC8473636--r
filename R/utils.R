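# Shared helpers: seeded RNG scopes, seed derivation, validation.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Integer-overflow-safe seed offset, kept below 2^31.
seed_add <- function(seed, k) as.integer((as.numeric(seed) + k) %% 2147483629)

# Deterministically derive k child seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k, replace = FALSE))
}

# Named child seed for a pipeline stage: stable across runs and platforms.
stage_seed <- function(seed, stage) {
  stages <- c("phantom", "augment", "gan", "filter", "train", "explain",
              "split", "features")
  i <- match(stage, stages)
  if (is.na(i)) abort(paste0("unknown stage '", stage, "'"))
  derive_seeds(seed, length(stages))[i]
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(paste0("`", name, "` must be a single finite number"))
  if (integer && x != round(x))
    abort(paste0("`", name, "` must be an integer"))
  if (x < lower || x > upper)
    abort(paste0("`", name, "` must be in [", lower, ", ", upper, "], got ", x))
  invisible(x)
}

check_range <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] > x[2])
    abort(paste0("`", name, "` must be a non-empty closed interval c(lo, hi)"))
  if (x[1] < lower || x[2] > upper)
    abort(paste0("`", name, "` must lie within [", lower, ", ", upper, "]"))
  invisible(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

runif1 <- function(range) if (range[1] == range[2]) range[1] else runif(1, range[1], range[2])

is_pow2 <- function(x) x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
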