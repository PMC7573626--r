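# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# FNV-1a 32-bit hash of a character scalar, returned as a non-negative
# double < 2^31. Used for stable per-stage sub-seeds and config hashes;
# avoids a dependency on digest.
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h %% 2147483648
}

# bitwXor on doubles holding 32-bit unsigned values
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

# Stable hash of an R object via its deparsed form.
config_hash <- function(x) {
  sprintf("%08x", fnv1a(paste(deparse(x, control = "all"), collapse = "\n")))
}

# Derive a reproducible sub-seed from a parent seed and a label.
derive_seed <- function(seed, label) {
  as.integer((fnv1a(paste0(label, ":", format(seed))) + as.double(seed)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate a right-continuous step function defined by (times, values),
# with value `v0` on [0, times[1]).
step_eval <- function(times, values, t, v0 = 1) {
  idx <- findInterval(t, times)
  out <- c(v0, values)[idx + 1L]
  out
}
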