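#' Derive a stage seed from a master seed
#'
#' Runs of the pipeline derive one seed per named stage from a single master
#' seed so that any stage can be re-run independently and reproducibly.  The
#' derivation is a small deterministic hash of the stage name folded into the
#' master seed, kept strictly below 2^31 so it is always a valid R integer.
#'
#' @param master Master seed (single integer).
#' @param stage Stage name (character scalar).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "founders")
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(stage),
            length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  as.integer(h %% (m - 1) + 1)
}

# clamp a numeric vector into [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# run expr with a local RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits
fnv1a32 <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    # xor on the low 31 bits plus explicit top bit (bitwXor needs ints)
    top <- h >= 2147483648
    h31 <- h - top * 2147483648
    h <- bitwXor(as.integer(h31), as.integer(b)) + top * 2147483648
    # multiply by the FNV prime 16777619 = 2^24 + 403 modulo 2^32,
    # split so every intermediate stays exactly representable in a double
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
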