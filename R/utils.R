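`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

# Nearest-rank quantile: rank ceil(q*n), 1-based on the ascending sort.
# A small tolerance guards against q*n landing epsilon above an integer
# (e.g. 0.05 * 100 = 5.000000000000001 in double arithmetic).
nearest_rank <- function(q, n) {
  r <- ceiling(q * n - 1e-9)
  max(1L, min(n, as.integer(r)))
}

fmt_distance <- function(x) sprintf("%.6f", x)
fmt_pvalue <- function(x) sprintf("%.4e", x)
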