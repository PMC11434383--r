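#' Normalize a raw sequence to the canonical RNA alphabet
#'
#' Strips whitespace, uppercases, and converts T to U so that DNA-alphabet
#' input from public piRNA databases maps onto the RNA descriptor definitions.
#' Idempotent.
#'
#' @param raw non-empty character scalar.
#' @return canonical RNA string over \{A,C,G,U\}.
#' @examples
#' normalizeSequence("atcg")  # "AUCG"
#' @export
normalizeSequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L)
    stop("'raw' must be a single character string")
  s <- gsub("[[:space:]]+", "", raw)
  if (!nzchar(s)) stop("sequence is empty after removing whitespace")
  s <- chartr("T", "U", toupper(s))
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at position %d (alphabet is A,C,G,U)",
                 substr(s, bad, bad), bad))
  s
}

#' Read piRNA sequences from a FASTA file
#'
#' Sequences are normalized via [normalizeSequence()] (so DNA-alphabet FASTA
#' is accepted) and all records receive the given class label. Record order is
#' preserved; the id is the first whitespace-delimited token of each header.
#'
#' @param path FASTA file (single- or multi-line sequences).
#' @param label class label for every record: "selected", "random" or
#'   "unknown".
#' @return a [PiRNASet-class].
#' @export
readPiRNAFasta <- function(path, label = "unknown") {
  label <- match.arg(label, .LABELS)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vapply(as.character(set), normalizeSequence, character(1),
                 USE.NAMES = FALSE)
  names(seqs) <- ids
  PiRNASet(seqs, labels = label)
}

#' Write a PiRNASet as FASTA (plus an optional label table)
#'
#' @param x a [PiRNASet-class].
#' @param path output FASTA path.
#' @param labelPath optional path for a two-column (id, label) TSV.
#' @return `path`, invisibly.
#' @export
writePiRNAFasta <- function(x, path, labelPath = NULL) {
  stopifnot(is(x, "PiRNASet"))
  Biostrings::writeXStringSet(x@sequences, filepath = path)
  if (!is.null(labelPath))
    write.table(data.frame(id = names(x), label = x@labels),
                labelPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.ID_LIST_NAMES <- c("crc_training", "random_training",
                    "crc_independent", "breast_independent")

#' Load a packaged piRNA identifier list
#'
#' Four identifier panels ship with the package: the 13 colorectal-cancer
#' (CRC) associated training piRNAs, 13 background ("random") training ids,
#' 7 independent CRC-associated validation piRNAs, and 9 breast-cancer
#' piRNAs used as a CRC-unrelated control. Only identifiers are packaged;
#' sequences are supplied by the user as FASTA. The random_training panel is
#' a frozen synthetic stand-in (see the file header under
#' `inst/extdata/id_lists/`), since the original random draw was never
#' published.
#'
#' @param name one of "crc_training", "random_training", "crc_independent",
#'   "breast_independent".
#' @return an [IdList-class].
#' @examples
#' loadPackagedIdList("crc_training")
#' @export
loadPackagedIdList <- function(name) {
  if (!name %in% .ID_LIST_NAMES)
    stop("unknown id list '", name, "'; valid names: ",
         paste(.ID_LIST_NAMES, collapse = ", "))
  path <- system.file("extdata", "id_lists", paste0(name, ".txt"),
                      package = "piRNAdx", mustWork = TRUE)
  lines <- readLines(path)
  ids <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  new("IdList", name = name, ids = ids)
}

#' Write a feature table as TSV
#'
#' One instance per row: an `id` column, one column per descriptor (header =
#' descriptor names), and a final `label` column. Values are written at full
#' precision.
#'
#' @param features a [PiRNAFeatures-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTSV <- function(features, path) {
  stopifnot(is(features, "PiRNAFeatures"))
  m <- featureMatrix(features)
  df <- data.frame(id = rownames(m), m, label = classLabels(features),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [writeFeatureTSV()]
#'
#' @param path TSV path.
#' @return a [PiRNAFeatures-class].
#' @export
readFeatureTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% colnames(df)))
    stop("feature TSV must contain 'id' and 'label' columns: ", path)
  descr <- setdiff(colnames(df), c("id", "label"))
  m <- t(as.matrix(df[, descr, drop = FALSE]))
  colnames(m) <- df$id
  PiRNAFeatures(m, labels = df$label)
}
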