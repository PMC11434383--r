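# Class entropy in bits from an integer label vector (codes 1..K).
.entropyCodes <- function(codes, K) {
  p <- tabulate(codes, nbins = K)
  p <- p[p > 0] / length(codes)
  -sum(p * log2(p))
}

# Recursive Fayyad-Irani split on sorted values/codes. Returns cut points.
.mdlCutsSorted <- function(v, codes, K) {
  n <- length(v)
  if (n < 2L) return(numeric(0))
  cand <- which(diff(v) > 0)
  if (!length(cand)) return(numeric(0))
  entS <- .entropyCodes(codes, K)
  kS <- length(unique(codes))
  best <- 0L; bestW <- Inf; bestE1 <- 0; bestE2 <- 0
  for (i in cand) {
    e1 <- .entropyCodes(codes[seq_len(i)], K)
    e2 <- .entropyCodes(codes[(i + 1L):n], K)
    w <- (i * e1 + (n - i) * e2) / n
    if (w < bestW - 1e-12) {
      bestW <- w; best <- i; bestE1 <- e1; bestE2 <- e2
    }
  }
  gain <- entS - bestW
  k1 <- length(unique(codes[seq_len(best)]))
  k2 <- length(unique(codes[(best + 1L):n]))
  # MDL acceptance: gain must exceed
  # [log2(n-1) + log2(3^k - 2) - k*E(S) + k1*E(S1) + k2*E(S2)] / n
  delta <- log2(3^kS - 2) - (kS * entS - k1 * bestE1 - k2 * bestE2)
  if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  cut <- (v[best] + v[best + 1L]) / 2
  left <- seq_len(best); right <- (best + 1L):n
  sort(c(.mdlCutsSorted(v[left], codes[left], K), cut,
         .mdlCutsSorted(v[right], codes[right], K)))
}

#' Fayyad-Irani MDL discretization of a numeric feature
#'
#' Recursive binary splitting on the boundary that minimizes weighted class
#' entropy; each split is accepted only when its information gain exceeds the
#' minimum-description-length threshold
#' \deqn{[\log_2(n-1) + \log_2(3^k - 2) - k E(S) + k_1 E(S_1) + k_2 E(S_2)]/n,}
#' where \eqn{k}, \eqn{k_1}, \eqn{k_2} count the classes present in the parent
#' and child subsets and \eqn{E} is class entropy in bits. A feature that
#' never justifies a split yields no cut points (and so zero gain).
#'
#' @param values numeric feature values.
#' @param labels class labels, same length.
#' @return ascending numeric cut points (possibly empty).
#' @examples
#' mdlDiscretize(c(1, 2, 3, 4), c("a", "a", "b", "b"))  # 2.5
#' @export
mdlDiscretize <- function(values, labels) {
  if (length(values) != length(labels))
    stop("'values' and 'labels' must have the same length")
  if (length(values) < 2L) return(numeric(0))
  codes <- as.integer(factor(labels))
  o <- order(values)
  .mdlCutsSorted(values[o], codes[o], K = max(codes))
}

#' Information gain of a discretized feature, in bits
#'
#' Bins `values` at the given ascending cut points and returns
#' \eqn{H(\mathrm{labels}) - \sum_v p(v) H(\mathrm{labels} \mid \mathrm{bin}\ v)}
#' with base-2 logarithms. With no cut points there is a single bin and the
#' gain is 0.
#'
#' @param values numeric feature values.
#' @param labels class labels, same length.
#' @param cuts ascending numeric cut points from [mdlDiscretize()].
#' @return information gain in bits, in \[0, log2(#classes)\].
#' @export
infoGain <- function(values, labels, cuts = mdlDiscretize(values, labels)) {
  if (length(values) != length(labels))
    stop("'values' and 'labels' must have the same length")
  if (!length(cuts)) return(0)
  codes <- as.integer(factor(labels))
  K <- max(codes)
  bins <- findInterval(values, cuts)
  cond <- 0
  for (b in unique(bins)) {
    idx <- bins == b
    cond <- cond + mean(idx) * .entropyCodes(codes[idx], K)
  }
  .entropyCodes(codes, K) - cond
}

#' Rank descriptors by information gain
#'
#' Each descriptor is discretized with [mdlDiscretize()] against the class
#' labels, its information gain computed, and all descriptors sorted by
#' decreasing gain with ties broken by canonical schema order (the row order
#' of the feature container), so the ranking is deterministic and invariant
#' to instance order.
#'
#' @param features a [PiRNAFeatures-class] with at least 2 instances and both
#'   classes present.
#' @return an [InfoGainRanking-class].
#' @export
rankDescriptors <- function(features) {
  stopifnot(is(features, "PiRNAFeatures"))
  labels <- classLabels(features)
  if (length(unique(labels)) < 2L)
    stop("descriptor ranking requires at least two classes")
  m <- SummarizedExperiment::assay(features, "descriptors")
  codes <- as.integer(factor(labels))
  K <- max(codes)
  gains <- vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    o <- order(v)
    cuts <- .mdlCutsSorted(v[o], codes[o], K)
    if (!length(cuts)) return(0)
    infoGain(v, labels, cuts)
  }, numeric(1))
  ord <- order(-gains, seq_along(gains))
  new("InfoGainRanking", descriptor = rownames(m)[ord], gain = gains[ord])
}

#' Reduce a feature table to its most informative descriptors
#'
#' @param features a [PiRNAFeatures-class].
#' @param ranking an [InfoGainRanking-class] for the same descriptors.
#' @param rule "positive_gain" keeps every descriptor with gain > 0 (the
#'   default); "top_k" keeps the `k` best-ranked descriptors.
#' @param k number of descriptors for "top_k" (default 27).
#' @return a [PiRNAFeatures-class] restricted to the chosen descriptors, in
#'   schema order, labels untouched.
#' @export
selectDescriptors <- function(features, ranking = rankDescriptors(features),
                              rule = c("positive_gain", "top_k"), k = 27L) {
  rule <- match.arg(rule)
  stopifnot(is(features, "PiRNAFeatures"), is(ranking, "InfoGainRanking"))
  keep <- switch(rule,
    positive_gain = ranking@descriptor[ranking@gain > 0],
    top_k = {
      if (k < 1L) stop("k must be >= 1")
      if (k > length(ranking@descriptor))
        stop(sprintf("k = %d exceeds the %d available descriptors", k,
                     length(ranking@descriptor)))
      ranking@descriptor[seq_len(k)]
    })
  if (!length(keep))
    stop("empty selection: no descriptor has positive information gain")
  sel <- features[rownames(features) %in% keep, ]
  S4Vectors::metadata(sel)$selection <-
    list(rule = rule, k = if (rule == "top_k") as.integer(k) else NA_integer_,
         descriptors = rownames(sel))
  sel
}

#' Export a ranking as a data.frame or TSV
#'
#' @param ranking an [InfoGainRanking-class].
#' @param path optional TSV path; when given the table is also written there.
#' @return data.frame with columns descriptor, gain, rank.
#' @export
rankingTable <- function(ranking, path = NULL) {
  df <- data.frame(descriptor = ranking@descriptor, gain = ranking@gain,
                   rank = seq_along(ranking@gain))
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
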