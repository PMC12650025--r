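# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All user-facing randomness goes through this so a
# single integer seed makes any operation reproducible without clobbering the
# session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-stage seed derivation from one global seed. Offsets are
# fixed so partial reruns of a pipeline stay reproducible; results stay inside
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101L + offset) %% 2147483647)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Pearson correlation between two topographic maps (across channels).
# Degenerate (zero-variance) maps yield 0 rather than NA so that argmax-based
# assignment stays well defined on flat samples.
spatial_corr <- function(a, b) {
  a <- a - mean(a)
  b <- b - mean(b)
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    return(0)
  }
  sum(a * b) / (na * nb)
}

# Zero-mean, unit-L2-norm version of a map (average-reference convention).
normalize_map <- function(v) {
  v <- v - mean(v)
  n <- sqrt(sum(v * v))
  if (n == 0) {
    return(v)
  }
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
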