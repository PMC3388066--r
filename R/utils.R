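# Internal helpers shared across modules.

# Signal a classed error so callers can condition on failure modes.
abort2 <- function(message, class, ...) {
  stop(structure(
    class = c(class, "prdm9znf_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation: keeps derived seeds inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp with per-row weights w (length = ncol(x)).
logsumexp_rows <- function(x, logw) {
  x <- sweep(x, 2L, logw, `+`)
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stopifnot_string <- function(x, what) {
  if (!is_string(x)) abort2(sprintf("%s must be a single string", what), "bad_input")
}
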