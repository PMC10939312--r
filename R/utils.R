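# Internal helpers shared across modules.

# Deterministic seed derivation: a rolling-hash of the master seed and any
# number of integer indices (participant, repetition, stage ...), kept inside
# the 32-bit integer range. Any sub-stream is reproducible in isolation.
derive_seed <- function(master, ...) {
  ix <- c(...)
  s <- as.double(master) %% 2147483629
  for (i in ix) s <- (s * 31 + as.double(i) + 1) %% 2147483629
  as.integer(s)
}

# OLS slope of y over the index 1..length(y), as closed-form weights.
ols_slope_weights <- function(n) {
  x <- seq_len(n)
  xc <- x - mean(x)
  xc / sum(xc^2)
}

index_slope <- function(y) sum(ols_slope_weights(length(y)) * y)

# Row-wise z-scoring of a pattern matrix (patterns x voxels).
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- sqrt(pmax(rowSums((m - mu)^2) / (ncol(m) - 1), 0))
  if (any(sd == 0))
    stop("zero-variance pattern: ",
         paste(which(sd == 0), collapse = ", "))
  (m - mu) / sd
}

# Equal-count binning of ranks 1..n into `bins` bins; remainders go to the
# lower bins so the assignment is deterministic.
equal_count_bins <- function(values, bins = 10L) {
  n <- length(values)
  if (n < bins) stop("need at least ", bins, " values to form ", bins, " bins")
  base <- n %/% bins
  rem <- n %% bins
  sizes <- rep(base, bins) + c(rep(1L, rem), rep(0L, bins - rem))
  bin_of_rank <- rep(seq_len(bins), times = sizes)
  bin_of_rank[rank(values, ties.method = "first")]
}

offdiag_mean <- function(m) {
  (sum(m) - sum(diag(m))) / (length(m) - nrow(m))
}
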