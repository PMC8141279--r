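#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
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

# Derive a deterministic per-stage seed from a master seed and a stream name,
# so each generator draws from an independent, individually reproducible
# substream. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131L)
  as.integer((as.numeric(master) * 69069 + h) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

# 1-based CpG position -> 0-based half-open point used for interval work.
pos_to_point0 <- function(pos) as.integer(pos) - 1L

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(x == floor(x))
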