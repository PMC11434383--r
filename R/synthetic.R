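#' Configuration for the synthetic piRNA generator
#'
#' Describes the study design the generator emulates: two classes of
#' piRNA-scale sequences (lengths uniform on 24-31 nt by default) drawn from
#' a background nucleotide composition, with chosen motifs written into the
#' positive ("selected") class at a given per-sequence insertion probability,
#' optionally restricted to the first-five or last-five nucleotide window.
#'
#' @param n_per_class sequences per class.
#' @param length_range integer pair, inclusive length bounds (>= 5).
#' @param background_freqs named numeric over A,C,G,U summing to 1.
#' @param planted_motifs list of `list(motif =, region =, prob =)` entries;
#'   `region` is one of "anywhere", "first5", "last5".
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   the config.
#' @return a validated config (classed list).
#' @examples
#' cfg <- generatorConfig(n_per_class = 13,
#'   planted_motifs = list(list(motif = "CAG", region = "first5", prob = 0.9)))
#' @export
generatorConfig <- function(n_per_class,
                            length_range = c(24L, 31L),
                            background_freqs = c(A = 0.25, C = 0.25,
                                                 G = 0.25, U = 0.25),
                            planted_motifs = list(),
                            seed = 1L) {
  stopifnot(n_per_class >= 1, length(length_range) == 2)
  if (length_range[1] < 5L) stop("minimum sequence length is 5")
  if (length_range[1] > length_range[2]) stop("invalid length range")
  background_freqs <- background_freqs[.RNA_ALPHABET]
  if (anyNA(background_freqs) || abs(sum(background_freqs) - 1) > 1e-9)
    stop("background_freqs must be named over A,C,G,U and sum to 1")
  for (pm in planted_motifs) {
    if (!all(c("motif", "region", "prob") %in% names(pm)))
      stop("each planted motif needs 'motif', 'region' and 'prob'")
    if (grepl("[^ACGU]", pm$motif)) stop("motifs must be over A,C,G,U")
    if (!pm$region %in% c("anywhere", "first5", "last5"))
      stop("region must be 'anywhere', 'first5' or 'last5'")
    maxlen <- if (pm$region == "anywhere") length_range[1] else 5L
    if (nchar(pm$motif) > maxlen)
      stop(sprintf("motif '%s' does not fit region '%s'", pm$motif,
                   pm$region))
    if (pm$prob < 0 || pm$prob > 1) stop("insertion prob must be in [0,1]")
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 background_freqs = background_freqs,
                 planted_motifs = planted_motifs,
                 seed = as.integer(seed)),
            class = "piRNAGeneratorConfig")
}

#' Generate a labeled synthetic piRNA set
#'
#' Sequence letters are i.i.d. from the background composition and lengths
#' uniform on the configured range for both classes; each planted motif is
#' then written into positive-class sequences with its insertion probability,
#' overwriting the background letters at a uniformly chosen in-region
#' position (so sequence length never leaks the label). A single seeded
#' random stream determines the whole dataset.
#'
#' @param config a config from [generatorConfig()].
#' @return a [PiRNASet-class] with `n_per_class` "selected" followed by
#'   `n_per_class` "random" sequences.
#' @export
generatePiRNAs <- function(config) {
  stopifnot(inherits(config, "piRNAGeneratorConfig"))
  set.seed(config$seed)
  n <- config$n_per_class
  lens <- sample(seq(config$length_range[1], config$length_range[2]),
                 2L * n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(.RNA_ALPHABET, L, replace = TRUE,
                 prob = config$background_freqs), collapse = ""),
    character(1))
  labels <- rep(c("selected", "random"), each = n)
  for (i in seq_len(n)) {  # positives are the first n
    occupied <- integer(0)  # positions already holding a planted motif
    for (pm in config$planted_motifs) {
      if (stats::runif(1) > pm$prob) next
      L <- lens[i]; m <- nchar(pm$motif)
      bounds <- switch(pm$region,
        anywhere = c(1L, L - m + 1L),
        first5 = c(1L, min(5L, L) - m + 1L),
        last5 = c(max(1L, L - 4L), L - m + 1L))
      starts <- seq(bounds[1], max(bounds))
      # do not overwrite motifs planted earlier in this sequence, so every
      # insertion event is actually present in the final string
      free <- starts[vapply(starts, function(p)
        !any(seq(p, p + m - 1L) %in% occupied), logical(1))]
      if (!length(free)) free <- starts
      pos <- free[sample.int(length(free), 1L)]
      substr(seqs[i], pos, pos + m - 1L) <- pm$motif
      occupied <- c(occupied, seq(pos, pos + m - 1L))
    }
  }
  ids <- sprintf("syn-%s-%03d", ifelse(labels == "selected", "pos", "neg"),
                 c(seq_len(n), seq_len(n)))
  PiRNASet(setNames(seqs, ids), labels = labels)
}

.PRESETS <- c("separable", "null", "paper_like")

# The three planted motifs used by the motif-enriched presets: one in the
# first-5 window, one in the last-5 window, one anywhere.
.PRESET_MOTIFS <- function(prob) list(
  list(motif = "CAG", region = "first5", prob = prob),
  list(motif = "UGA", region = "last5", prob = prob),
  list(motif = "AGGC", region = "anywhere", prob = prob))

#' Preset benchmark configurations
#'
#' `"paper_like"` mirrors the scale of the real study design: 13 sequences
#' per class with three planted motifs (first-5 "CAG", last-5 "UGA",
#' anywhere "AGGC") at insertion probability 0.9. `"separable"` plants the
#' same motifs deterministically (probability 1). `"null"` plants no motifs
#' and uses 50 sequences per class, so labels carry no sequence signal.
#'
#' @param preset one of "separable", "null", "paper_like".
#' @param seed integer seed (default 1).
#' @return a config from [generatorConfig()].
#' @export
presetConfig <- function(preset, seed = 1L) {
  if (!preset %in% .PRESETS)
    stop("unknown preset '", preset, "'; valid presets: ",
         paste(.PRESETS, collapse = ", "))
  switch(preset,
    paper_like = generatorConfig(13L, planted_motifs = .PRESET_MOTIFS(0.9),
                                 seed = seed),
    separable = generatorConfig(13L, planted_motifs = .PRESET_MOTIFS(1.0),
                                seed = seed),
    null = generatorConfig(50L, seed = seed))
}

#' Featurized benchmark dataset for a preset
#'
#' Convenience wrapper: [presetConfig()] then [generatePiRNAs()] then
#' [featurize()].
#'
#' @inheritParams presetConfig
#' @param schema a [DescriptorSchema-class].
#' @return a [PiRNAFeatures-class] (1020 descriptors x 2 * n instances).
#' @examples
#' dim(benchmarkDataset("paper_like"))  # 1020 x 26
#' @export
benchmarkDataset <- function(preset, seed = 1L, schema = buildSchema()) {
  featurize(generatePiRNAs(presetConfig(preset, seed = seed)), schema)
}
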