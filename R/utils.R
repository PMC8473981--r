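# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` runs unseeded.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  expr
}

# Derive a reproducible child seed (kept below 2^31) from a parent seed.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 2654435761 + 97 * as.double(index)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# YAML 1.1 parses a bare Y/N as logical; map back to haplotype labels.
normalize_hap <- function(x) {
  if (is.logical(x)) return(ifelse(x, "Y", "S"))
  as.character(x)
}
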