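`%||%` <- function(x, y) if (is.null(x)) y else x

#' Deterministic substream seed
#'
#' Derives a 31-bit seed from a master seed and a stream name, so each named
#' source of randomness gets its own reproducible stream and adding a new
#' generator never perturbs existing ones.
#'
#' @param seed master integer seed.
#' @param name character stream name, e.g. `"bootstrap:17"`.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(name) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(enc2utf8(as.character(name)))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer((h + (abs(as.numeric(seed)) %% m) * 7919) %% m)
}

# FNV-1a over a character scalar; used to stamp report bundles with a
# configuration fingerprint without a hashing dependency.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648 - (h >= 2147483648) * 0), b)
    # keep arithmetic in doubles below 2^53
    h <- (abs(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

# Presentation rounding; base round() implements round-half-to-even, which is
# the convention the report tables use.
round_half_even <- function(x, digits = 4) round(x, digits)
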