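# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All package-level determinism contracts go
# through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministically derive a child seed from a master seed and a stream
# label, so data order, DropKey, denoising noise etc. draw from independent
# streams that still fan out from one seed. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629 + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  m <- max(x[is.finite(x)], -Inf)
  if (!is.finite(m)) return(rep(NA_real_, length(x)))
  e <- exp(x - m)
  e[!is.finite(x) & x < 0] <- 0
  e / sum(e)
}

# Row-wise softmax with -Inf support (fully masked rows return NA rows).
softmax_rows <- function(x) {
  res <- apply(x, 1L, softmax)
  if (is.null(dim(res))) matrix(res, ncol = 1L) else t(res)
}
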