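#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All randomness in the package funnels
# through this helper so that seeds never leak between operations.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

# Row-wise softmax with an optional logical mask; masked-out entries get
# probability 0 and fully masked rows return all-zero rows.
masked_row_softmax <- function(x, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  z <- ifelse(mask, x, -Inf)
  m <- apply(z, 1L, max)
  ok <- is.finite(m)
  out <- matrix(0, nrow(x), ncol(x))
  if (any(ok)) {
    e <- exp(z[ok, , drop = FALSE] - m[ok])
    e[!is.finite(e)] <- 0
    out[ok, ] <- e / rowSums(e)
  }
  dimnames(out) <- dimnames(x)
  out
}

elu <- function(x) ifelse(x > 0, x, expm1(x))
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) stats::plogis(x)

# L2-normalize matrix rows; all-zero rows are returned unchanged so that a
# ReLU that silences a row can never produce NaN downstream.
l2_normalize_rows <- function(x) {
  x <- as.matrix(x)
  nrm <- sqrt(rowSums(x^2))
  nz <- nrm > 0
  x[nz, ] <- x[nz, , drop = FALSE] / nrm[nz]
  x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("non-finite values in %s", what)
  invisible(x)
}
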