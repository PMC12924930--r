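# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. All stochastic entry points
# funnel through this so a single integer seed makes a run reproducible.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed and a stream index, staying
# within 32-bit integer range.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647L)
}

stopifnot_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  if (strict && x <= min) stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  if (!strict && x < min) stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  invisible(x)
}

# Euclidean distance matrix (dense, base R).
dist_matrix <- function(xy) {
  as.matrix(stats::dist(xy))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
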