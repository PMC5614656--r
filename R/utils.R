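# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed; global RNG state untouched.
# seed = NULL means "use the current stream" (no isolation).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic sub-seed from a master seed and a key (number or string).
# Keeps the result strictly inside the 32-bit signed-integer range.
derive_seed <- function(seed, key) {
  if (is.character(key)) key <- sum(utf8ToInt(key))
  v <- (as.numeric(seed) * 48271 + round(as.numeric(key) * 1000003)) %% 2147483587
  as.integer(abs(v))
}

# Sort each row of a numeric matrix in decreasing order without an
# apply() loop: one order() call on (row index, -value).
sort_rows_desc <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (m == 1L) return(x)
  o <- order(rep.int(seq_len(n), m), -as.vector(x))
  matrix(as.vector(x)[o], nrow = n, ncol = m, byrow = TRUE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
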