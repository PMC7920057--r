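`%||%` <- function(x, y) if (is.null(x)) y else x

stop_invalid <- function(...) {
  stop(structure(class = c("adaptherapy_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_invalid(what, " must be finite numeric")
  }
  invisible(x)
}

# FNV-1a hash of a character scalar; used to fingerprint run configs in
# output manifests without an external digest dependency.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits; do it in double space
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619, split into 16-bit
    # halves so every intermediate stays exact in double precision
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", (h - lo) / 65536, lo)
}

# Derive a stream of child seeds (< 2^31) from one master seed without
# disturbing the caller's RNG state more than once.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
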