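# Independent oracles used to cross-check the implementation. These are kept
# deliberately naive (rescanning, enumeration, closed forms) and never call
# the code paths they verify.

# Overlapping occurrences of `motif` in `seq` by rescanning every position.
naiveMotifCount <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(0L)
  sum(vapply(seq_len(n - m + 1L),
             function(i) substr(seq, i, i + m - 1L) == motif, logical(1)))
}

# Full naive k-mer count vector by substring extraction + table().
naiveKmerVector <- function(seq, k) {
  motifs <- sort(do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "U")),
                                                 k))[, k:1, drop = FALSE]))
  out <- setNames(integer(length(motifs)), motifs)
  n <- nchar(seq)
  if (n >= k) {
    subs <- substring(seq, 1:(n - k + 1), k:n)
    tab <- table(subs)
    out[names(tab)] <- as.integer(tab)
  }
  out
}

# Class entropy in bits, from scratch.
naiveEntropy <- function(labels) {
  p <- as.vector(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Information gain of a binned feature, computed with table()/split().
naiveInfoGain <- function(values, labels, cuts) {
  if (!length(cuts)) return(0)
  bins <- cut(values, breaks = c(-Inf, cuts, Inf))
  gain <- naiveEntropy(labels)
  for (grp in split(labels, bins)) {
    if (!length(grp)) next
    gain <- gain - (length(grp) / length(labels)) * naiveEntropy(grp)
  }
  gain
}

# The Fayyad-Irani acceptance check, evaluated directly for a single split.
naiveMdlAccepts <- function(values, labels, cut) {
  left <- labels[values <= cut]; right <- labels[values > cut]
  n <- length(labels)
  k <- length(unique(labels))
  k1 <- length(unique(left)); k2 <- length(unique(right))
  gain <- naiveEntropy(labels) -
    (length(left) * naiveEntropy(left) +
     length(right) * naiveEntropy(right)) / n
  thr <- (log2(n - 1) + log2(3^k - 2) - k * naiveEntropy(labels) +
          k1 * naiveEntropy(left) + k2 * naiveEntropy(right)) / n
  gain > thr
}

# AUC as the concordant-pair fraction (ties count 1/2).
naiveAUC <- function(scores, labels, positive = "selected") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}

# Uniform random RNA string, independent of the package generator.
randomRNA <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Small labeled toy feature container built by hand.
toyFeatures <- function(mat, labels) {
  PiRNAFeatures(t(mat), labels = labels)
}

writeTempFasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}
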