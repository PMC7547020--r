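# Internal helpers: scoped RNG and stable string hashing.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous state so library code never perturbs the user's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# FNV-1a over the UTF-8 bytes of a string, folded to a positive 31-bit
# integer. Used to derive per-genome evaluation seeds that depend only on the
# genome content, never on execution order; must stay stable across platforms.
# Arithmetic is done in doubles with an explicit split multiply so every
# intermediate stays below 2^53.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  prime <- 16777619
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# Derive a child seed from a master seed and a string key; stays below 2^31.
derive_seed <- function(master_seed, key) {
  as.integer((as.double(master_seed) + as.double(fnv1a32(key))) %% 2147483647)
}

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
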