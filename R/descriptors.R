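# Average nucleobase masses in daltons. The mass table is a schema parameter:
# pass a different one to buildSchema() to change the Mass/N descriptor.
.DEFAULT_MASSES <- c(A = 135.13, C = 111.10, G = 151.13, U = 112.09)
# Watson-Crick pairing capacity.
.DEFAULT_HBONDS <- c(A = 2, C = 3, G = 3, U = 2)

.GLOBAL_NAMES <- c("N", "A", "G", "C", "U", "A/N", "G/N", "C/N", "U/N",
                   "Mass/N", "Hbonds", "Symmetry")

# All k-mers over A<C<G<U in lexicographic order, matching the column order
# of Biostrings::oligonucleotideFrequency on RNA input.
.kmerNames <- function(k) {
  grid <- expand.grid(rep(list(.RNA_ALPHABET), k),
                      stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  do.call(paste0, grid)
}

#' Build the canonical descriptor schema
#'
#' The 1020 descriptors decompose as 12 global descriptors, then overlapping
#' 2-, 3- and 4-mer motif counts over the full sequence (16 + 64 + 256 = 336
#' names, lexicographic over A<C<G<U), then the same motif enumeration
#' restricted to the first five nucleotides (prefix "5s") and to the last
#' five (prefix "5e"). The global block is, in order: N (length), A, G, C, U
#' (counts), A/N, G/N, C/N, U/N (frequencies), Mass/N (mean base mass in Da),
#' Hbonds (total hydrogen-bond capacity, A,U = 2 and G,C = 3), and Symmetry
#' (positions at which the sequence equals its reverse).
#'
#' @param masses named numeric nucleotide mass table in daltons; the default
#'   is the average nucleobase masses.
#' @param hbonds named numeric hydrogen-bond capacities.
#' @return a [DescriptorSchema-class] with 1020 unique names.
#' @examples
#' sch <- buildSchema()
#' length(schemaNames(sch))           # 1020
#' head(schemaNames(sch), 12)         # the global block
#' @export
buildSchema <- function(masses = .DEFAULT_MASSES, hbonds = .DEFAULT_HBONDS) {
  kmers <- unlist(lapply(2:4, .kmerNames))
  new("DescriptorSchema",
      names = c(.GLOBAL_NAMES, kmers, paste0("5s", kmers), paste0("5e", kmers)),
      masses = masses[.RNA_ALPHABET], hbonds = hbonds[.RNA_ALPHABET])
}

#' Descriptor names of a schema
#'
#' @param schema a [DescriptorSchema-class].
#' @return character vector of the 1020 ordered descriptor names.
#' @export
schemaNames <- function(schema) schema@names

#' Hash of a schema for provenance records
#'
#' MD5 over the ordered descriptor names and the mass and hydrogen-bond
#' tables, so any change to the descriptor definition changes the hash.
#'
#' @param schema a [DescriptorSchema-class].
#' @return character scalar MD5 hash.
#' @export
schemaHash <- function(schema) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(c(schema@names,
               sprintf("%s=%.6f", names(schema@masses), schema@masses),
               sprintf("%s=%g", names(schema@hbonds), schema@hbonds)), tf)
  unname(tools::md5sum(tf))
}

#' Export a schema as JSON
#'
#' @param schema a [DescriptorSchema-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeSchemaJSON <- function(schema, path) {
  jsonlite::write_json(
    list(names = schema@names, masses = as.list(schema@masses),
         hbonds = as.list(schema@hbonds), hash = schemaHash(schema)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Count overlapping k-mers in a sequence
#'
#' Every motif of length k over \{A,C,G,U\} is counted with overlaps (step 1);
#' motifs absent from the sequence map to 0. The counts over all 4^k motifs
#' sum to max(0, length - k + 1).
#'
#' @param seq normalized RNA string.
#' @param k motif length, one of 2, 3, 4.
#' @return named integer vector of length 4^k in lexicographic order.
#' @examples
#' countKmers("AAAAA", 2)[["AA"]]  # 4
#' @export
countKmers <- function(seq, k) {
  if (!k %in% 2:4) stop("k must be 2, 3 or 4")
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::RNAString(seq),
                                                 width = k)
  storage.mode(counts) <- "integer"
  counts
}

#' Mirror-symmetry score of a sequence
#'
#' The number of positions at which the sequence matches its reversed self
#' (positional identity against the mirror image, not the reverse
#' complement). Odd-length sequences always score at least 1 (the center).
#'
#' @param seq normalized RNA string.
#' @return integer symmetry count.
#' @examples
#' symmetryScore("AUUA")  # 4 (palindrome)
#' symmetryScore("AUCG")  # 0
#' @export
symmetryScore <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(ch == rev(ch))
}

#' The 12 global descriptors of a sequence
#'
#' @param seq normalized, non-empty RNA string.
#' @param schema a [DescriptorSchema-class] supplying the mass and
#'   hydrogen-bond tables.
#' @return named numeric vector: N, A, G, C, U, A/N, G/N, C/N, U/N, Mass/N,
#'   Hbonds, Symmetry.
#' @export
globalDescriptors <- function(seq, schema = buildSchema()) {
  if (!nzchar(seq)) stop("sequence is empty")
  n <- nchar(seq)
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::RNAString(seq),
                                                 width = 1)[.RNA_ALPHABET]
  out <- c(n, counts[c("A", "G", "C", "U")],
           counts[c("A", "G", "C", "U")] / n,
           sum(counts * schema@masses[.RNA_ALPHABET]) / n,
           sum(counts * schema@hbonds[.RNA_ALPHABET]),
           symmetryScore(seq))
  names(out) <- .GLOBAL_NAMES
  out
}

# descriptors x instances matrix for an RNAStringSet, in schema order
.featurizeSet <- function(set, schema) {
  w <- Biostrings::width(set)
  if (any(w == 0L)) stop("sequences must be non-empty")
  n <- length(set)
  counts1 <- Biostrings::oligonucleotideFrequency(set, width = 1)
  counts1 <- counts1[, .RNA_ALPHABET, drop = FALSE]
  sym <- vapply(as.character(set), symmetryScore, numeric(1),
                USE.NAMES = FALSE)
  globalBlock <- cbind(
    N = w,
    counts1[, c("A", "G", "C", "U"), drop = FALSE],
    counts1[, c("A", "G", "C", "U"), drop = FALSE] / w,
    `Mass/N` = as.vector(counts1 %*% schema@masses[.RNA_ALPHABET]) / w,
    Hbonds = as.vector(counts1 %*% schema@hbonds[.RNA_ALPHABET]),
    Symmetry = sym)
  colnames(globalBlock) <- .GLOBAL_NAMES

  kBlock <- function(s, prefix = "") {
    blk <- do.call(cbind, lapply(2:4, function(k)
      Biostrings::oligonucleotideFrequency(s, width = k)))
    if (nzchar(prefix)) colnames(blk) <- paste0(prefix, colnames(blk))
    blk
  }
  first5 <- Biostrings::subseq(set, 1L, pmin(w, 5L))
  last5 <- Biostrings::subseq(set, pmax(1L, w - 4L), w)
  mat <- t(cbind(globalBlock, kBlock(set), kBlock(first5, "5s"),
                 kBlock(last5, "5e")))
  stopifnot(identical(rownames(mat), schema@names))
  colnames(mat) <- names(set)
  mat
}

#' @rdname featurize
#' @export
setMethod("featurize", "character", function(x, schema = buildSchema(), ...) {
  x <- normalizeSequence(x)
  set <- Biostrings::RNAStringSet(setNames(x, "query"))
  .featurizeSet(set, schema)[, 1]
})

#' @rdname featurize
#' @export
setMethod("featurize", "PiRNASet", function(x, schema = buildSchema(), ...) {
  PiRNAFeatures(.featurizeSet(x@sequences, schema), labels = x@labels)
})
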