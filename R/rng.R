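# Seed derivation and RNG hygiene.
#
# Element-level sampling (loop thresholds, hidden lengths, critical strains)
# uses independent substreams so that, e.g., changing how many thresholds are
# drawn for one element never shifts the hidden-length samples of another.
# Substream seeds are derived by hashing (seed, label...) with FNV-1a; all
# arithmetic stays below 2^31 so seeds are valid R integers.

# 32-bit FNV-1a over the raw bytes of a string, done in double precision
# (exact: all intermediates < 2^53). The xor only ever touches the low byte,
# so it can use base bitwXor on the low 8 bits.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

#' Derive a reproducible substream seed
#'
#' Hashes a base seed together with an arbitrary set of labels into an
#' integer seed in `[0, 2^31 - 2]`. Used internally to give every element and
#' every sampled quantity its own independent random substream.
#'
#' @param seed Integer base seed.
#' @param ... Character or numeric labels identifying the substream.
#' @return A single integer seed.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  as.integer(fnv1a32(key) %% 2147483646)
}

# Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
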