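# Independent oracles used to cross-check the implementation.

# Plain-R semi-global affine-gap DP (read consumed in full, reference ends
# free; gap of length L costs open + (L - 1) * ext).  Written directly from
# the recurrences, independent of the compiled kernel.
oracleGlocalScore <- function(read, ref, match = 1, mismatch = -1,
                              open = 2, ext = 1) {
  n <- nchar(read); m <- nchar(ref)
  rc <- strsplit(read, "")[[1]]
  fc <- strsplit(ref, "")[[1]]
  M <- matrix(-Inf, n + 1, m + 1)
  D <- matrix(-Inf, n + 1, m + 1)
  I <- matrix(-Inf, n + 1, m + 1)
  for (i in 1:n) I[i + 1, 1] <- -(open + (i - 1) * ext)
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (rc[i] == fc[j]) match else mismatch
      prev <- if (i == 1) 0 else max(M[i, j], D[i, j], I[i, j])
      M[i + 1, j + 1] <- prev + s
      D[i + 1, j + 1] <- max(M[i + 1, j] - open, D[i + 1, j] - ext,
                             I[i + 1, j] - open)
      I[i + 1, j + 1] <- max(M[i, j + 1] - open, D[i, j + 1] - open,
                             I[i, j + 1] - ext)
    }
  }
  max(M[n + 1, ], I[n + 1, ])
}

# Exhaustive prefix edit distance via utils::adist over every prefix.
oraclePrefixEdit <- function(pattern, text) {
  min(vapply(0:nchar(text), function(j) {
    if (j == 0) nchar(pattern)
    else utils::adist(pattern, substr(text, 1, j))[1, 1]
  }, numeric(1)))
}

# Brute-force MID decoding: unique minimum distance tag within max_errors.
oracleMidMatch <- function(window, tags, max_errors = 2) {
  d <- vapply(tags, function(tg) oraclePrefixEdit(tg, window), numeric(1))
  best <- min(d)
  if (best > max_errors) return(NULL)
  hits <- names(tags)[d == best]
  if (length(hits) > 1) NULL else list(id = hits, errors = best)
}

# random DNA string
randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# apply k random substitutions within positions [from, to] of a string
mutateWindow <- function(seq, from, to, k) {
  chars <- strsplit(seq, "")[[1]]
  at <- sample(from:to, k)
  for (i in at) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}
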