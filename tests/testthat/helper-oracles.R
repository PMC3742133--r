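# Independent brute-force oracles, deliberately naive: these never share code
# with the package implementation.

# all 0-based offsets of pattern in sequence by sliding-window comparison
oracle_find <- function(sequence, pattern) {
  sequence <- toupper(sequence)
  pattern <- toupper(pattern)
  n <- nchar(sequence)
  m <- nchar(pattern)
  if (n < m) return(integer(0))
  starts <- 1:(n - m + 1)
  which(substring(sequence, starts, starts + m - 1) == pattern) - 1L
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# both-orientation hit offsets for a motif name
oracle_scan <- function(sequence, forward) {
  sort(c(oracle_find(sequence, forward),
         oracle_find(sequence, oracle_revcomp(forward))))
}

# count of unordered offset pairs with start-to-start distance in [lo, hi]
oracle_pair_count <- function(offsets, lo = 90, hi = 190) {
  k <- length(offsets)
  if (k < 2) return(0L)
  cnt <- 0L
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      d <- abs(offsets[j] - offsets[i])
      if (d >= lo && d <= hi) cnt <- cnt + 1L
    }
  }
  cnt
}

random_window <- function(len = 450, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
        collapse = "")
}

# a 450-nt window with given strings written at given 0-based offsets
window_with <- function(..., len = 450, fill = "T") {
  at <- list(...)
  s <- strrep(fill, len)
  for (p in at) {
    substr(s, p$offset + 1, p$offset + nchar(p$seq)) <- p$seq
  }
  s
}
site <- function(seq, offset) list(seq = seq, offset = offset)
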