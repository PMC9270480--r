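`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Stable hash of a configuration object
#'
#' 32-bit FNV-1a over the canonical JSON serialization; used to stamp
#' every pipeline artifact so reruns are auditable.
#'
#' @param x any jsonlite-serializable object.
#' @return an 8-character lowercase hex string.
#' @export
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- as.integer(charToRaw(as.character(js)))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- xor32(h, b)
    # h * p mod 2^32 in double arithmetic, split to stay under 2^53
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# bitwXor on values that may exceed .Machine$integer.max
xor32 <- function(a, b) {
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}
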