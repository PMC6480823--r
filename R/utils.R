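`%||%` <- function(a, b) if (is.null(a)) b else a

## lower-triangle (row-major) index pairs of an n x n symmetric matrix
vech_pairs <- function(n) {
  i <- rep(seq_len(n), times = seq_len(n))
  j <- unlist(lapply(seq_len(n), seq_len))
  cbind(row = i, col = j)
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

## derive a per-replication seed from a root seed (counter scheme, < 2^31)
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 7919 + as.double(counter) * 104729) %% 2147483647)
}
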