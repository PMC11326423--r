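# Internal helpers: seeded evaluation and deterministic seed derivation.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers user RNG.
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic 31-bit seed derived from a master seed and a stage label,
# so pipeline stages can be rerun independently with stable streams.
derive_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
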