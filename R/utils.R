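# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sigmoid <- function(v) 1 / (1 + exp(-v))

# binarization threshold used everywhere a chaotic iterate or uniform draw
# is turned into a bit: values >= 0.5 map to 1
binarize <- function(x) as.numeric(x >= 0.5)

bitKey <- function(position) paste(as.integer(position), collapse = "")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code does not clobber user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# Seeded shuffled fold assignment: returns a list of `k` index vectors
# partitioning 1..n, deterministic for a given seed.
makeFolds <- function(n, k, seed) {
  if (k < 2L) stop("at least 2 folds are required")
  if (k > n) stop("more folds (", k, ") than samples (", n, ")")
  perm <- withSeed(seed, sample.int(n))
  split(perm, rep_len(seq_len(k), n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
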