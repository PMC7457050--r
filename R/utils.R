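# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE, len = NULL) {
  if (!is.numeric(x)) stopf("`%s` must be numeric", name)
  if (!is.null(len) && length(x) != len)
    stopf("`%s` must have length %d", name, len)
  if (finite && any(!is.finite(x)))
    stopf("`%s` must be finite", name)
  if (positive && any(x <= 0))
    stopf("`%s` must be > 0", name)
  if (nonneg && any(x < 0))
    stopf("`%s` must be >= 0", name)
  invisible(x)
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so generators are pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stream sub-seed: one user-facing seed fans out to
# independent streams so adding a generator never perturbs existing fixtures.
derive_seed <- function(seed, stream) {
  h <- fnv1a32(paste0(format(as.integer(seed)), ":", stream))
  # keep strictly inside the 32-bit signed range R accepts for set.seed()
  as.integer(h %% 2147483629) + 1L
}

# FNV-1a 32-bit hash of a character scalar, done in doubles to avoid
# integer overflow; returns a non-negative double < 2^32.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor of two non-negative doubles < 2^32 (base bitwXor is integer-only)
bitwXor64 <- function(a, b) {
  r <- 0
  p <- 1
  for (i in 1:32) {
    r <- r + p * as.numeric(xor(a %% 2 >= 1, b %% 2 >= 1))
    a <- a %/% 2
    b <- b %/% 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

# stable content hash of an R object (used to stamp pipeline outputs)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- fnv1a32(as.character(s))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
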