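# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic substream seeds derived from one run seed, so each
# group/channel draws from an independent stream and partial re-runs
# reproduce. Kept strictly below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m) + 1
  for (i in seq_len(index)) {
    s <- (s * 48271) %% m
  }
  as.integer(s)
}

check_prob_vector <- function(p, what, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stopf("%s must be non-negative and finite", what)
  }
  if (abs(sum(p) - 1) > tol) {
    stopf("%s must sum to 1 (got %.12g)", what, sum(p))
  }
  invisible(p)
}

check_count <- function(x, what, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x)) {
    stopf("%s must be a single integer >= %d", what, min)
  }
  as.integer(x)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
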