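#' @import methods
#' @importFrom stats predict setNames rbinom
#' @importFrom utils head tail read.delim write.table
NULL

.LABELS <- c("selected", "random", "unknown")
.RNA_ALPHABET <- c("A", "C", "G", "U")

#' Canonical descriptor schema
#'
#' Holds the ordered names of the 1020 sequence descriptors together with the
#' per-nucleotide mass table (daltons, average nucleobase masses by default)
#' and hydrogen-bond capacities (A,U = 2; G,C = 3) used by the global
#' descriptors. Build one with [buildSchema()].
#'
#' @slot names ordered character vector of 1020 unique descriptor names.
#' @slot masses named numeric, nucleotide -> mass in Da.
#' @slot hbonds named numeric, nucleotide -> hydrogen-bond count.
#' @seealso [buildSchema()], [featurize()]
#' @export
setClass("DescriptorSchema",
  representation(names = "character", masses = "numeric", hbonds = "numeric"))

setValidity("DescriptorSchema", function(object) {
  msg <- character(0)
  if (length(object@names) != 1020L)
    msg <- c(msg, sprintf("schema must have 1020 names, has %d",
                          length(object@names)))
  if (anyDuplicated(object@names))
    msg <- c(msg, "descriptor names must be unique")
  for (slotname in c("masses", "hbonds")) {
    v <- slot(object, slotname)
    if (!identical(sort(names(v)), sort(.RNA_ALPHABET)))
      msg <- c(msg, sprintf("%s must be named over A,C,G,U", slotname))
  }
  if (length(msg)) msg else TRUE
})

#' A set of identified, normalized piRNA sequences with class labels
#'
#' Thin wrapper around a [Biostrings::RNAStringSet] whose names are the piRNA
#' identifiers, plus one class label per sequence ("selected" for
#' disease-associated, "random" for background, or "unknown").
#'
#' @slot sequences [Biostrings::RNAStringSet]; names are unique ids.
#' @slot labels character vector, one of "selected", "random", "unknown".
#' @seealso [readPiRNAFasta()], [generatePiRNAs()]
#' @export
setClass("PiRNASet",
  representation(sequences = "RNAStringSet", labels = "character"))

setValidity("PiRNASet", function(object) {
  msg <- character(0)
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (n == 0L) msg <- c(msg, "PiRNASet must contain at least one sequence")
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "all sequences must have non-empty ids")
  if (!is.null(ids) && anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@labels) != n)
    msg <- c(msg, "labels must match the number of sequences")
  if (!all(object@labels %in% .LABELS))
    msg <- c(msg, "labels must be 'selected', 'random' or 'unknown'")
  if (n > 0 && any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "sequences must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a PiRNASet
#'
#' @param sequences named character vector or [Biostrings::RNAStringSet]; raw
#'   character input is normalized via [normalizeSequence()].
#' @param labels class labels, recycled if scalar.
#' @return a [PiRNASet-class] object.
#' @examples
#' PiRNASet(c(p1 = "AUCGAUCG", p2 = "ggcuuacg"), labels = "selected")
#' @export
PiRNASet <- function(sequences, labels = "unknown") {
  if (is.character(sequences)) {
    norm <- vapply(sequences, normalizeSequence, character(1))
    names(norm) <- names(sequences)
    sequences <- Biostrings::RNAStringSet(norm)
  }
  if (length(labels) == 1L) labels <- rep(labels, length(sequences))
  new("PiRNASet", sequences = sequences, labels = labels)
}

setMethod("show", "PiRNASet", function(object) {
  cat(sprintf("PiRNASet with %d sequences (widths %d-%d)\n",
      length(object@sequences),
      min(Biostrings::width(object@sequences)),
      max(Biostrings::width(object@sequences))))
  cat("labels:",
      paste(sprintf("%s=%d", names(table(object@labels)),
                    table(object@labels)), collapse = " "), "\n")
})

#' @describeIn PiRNASet-class number of sequences.
#' @param x a PiRNASet.
#' @export
setMethod("length", "PiRNASet", function(x) length(x@sequences))

#' @describeIn PiRNASet-class sequence ids.
#' @export
setMethod("names", "PiRNASet", function(x) names(x@sequences))

#' Packaged piRNA identifier list
#'
#' @slot name list name (one of crc_training, random_training,
#'   crc_independent, breast_independent).
#' @slot ids ordered piRNA identifiers.
#' @seealso [loadPackagedIdList()]
#' @export
setClass("IdList", representation(name = "character", ids = "character"))

setValidity("IdList", function(object) {
  if (anyDuplicated(object@ids)) "duplicate ids in list" else TRUE
})

setMethod("show", "IdList", function(object) {
  cat(sprintf("IdList '%s': %d ids (%s, ...)\n", object@name,
      length(object@ids), paste(head(object@ids, 3), collapse = ", ")))
})

#' Instances-by-descriptors feature container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]: the "descriptors"
#' assay is descriptors x instances (Bioconductor orientation, features in
#' rows), `colData()$label` carries the class label. Use [featureMatrix()]
#' for the instances-by-descriptors matrix classifiers consume.
#'
#' @seealso [featurize()], [featureMatrix()], [classLabels()]
#' @export
setClass("PiRNAFeatures", contains = "SummarizedExperiment")

setValidity("PiRNAFeatures", function(object) {
  msg <- character(0)
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'label' column")
  else if (!all(object$label %in% .LABELS))
    msg <- c(msg, "labels must be 'selected', 'random' or 'unknown'")
  a <- SummarizedExperiment::assay(object)
  if (anyNA(a) || any(!is.finite(a)) || any(a < 0))
    msg <- c(msg, "descriptor values must be finite and >= 0")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "descriptor names must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a PiRNAFeatures object
#'
#' @param mat numeric matrix, descriptors x instances, with dimnames.
#' @param labels class label per instance.
#' @return a [PiRNAFeatures-class] object.
#' @export
PiRNAFeatures <- function(mat, labels) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(descriptors = mat),
    colData = S4Vectors::DataFrame(label = labels, row.names = colnames(mat)))
  new("PiRNAFeatures", se)
}

#' Information-gain ranking of descriptors
#'
#' Ordered (descriptor, gain-in-bits) pairs sorted by decreasing gain, ties
#' broken by canonical schema order.
#'
#' @slot descriptor character, descriptor names in rank order.
#' @slot gain numeric, information gain in bits.
#' @seealso [rankDescriptors()], [selectDescriptors()]
#' @export
setClass("InfoGainRanking",
  representation(descriptor = "character", gain = "numeric"))

setValidity("InfoGainRanking", function(object) {
  msg <- character(0)
  if (length(object@descriptor) != length(object@gain))
    msg <- c(msg, "descriptor and gain lengths differ")
  if (anyDuplicated(object@descriptor))
    msg <- c(msg, "duplicate descriptors in ranking")
  if (any(object@gain < -1e-12))
    msg <- c(msg, "gains must be non-negative")
  if (is.unsorted(rev(object@gain)))
    msg <- c(msg, "gains must be sorted in decreasing order")
  if (length(msg)) msg else TRUE
})

setMethod("show", "InfoGainRanking", function(object) {
  cat(sprintf("InfoGainRanking over %d descriptors (%d with positive gain)\n",
      length(object@gain), sum(object@gain > 0)))
  k <- min(5L, length(object@gain))
  for (i in seq_len(k))
    cat(sprintf("  %2d. %-10s %.4f bits\n", i, object@descriptor[i],
                object@gain[i]))
})

#' Multinomial naive Bayes model
#'
#' Class priors and Laplace-smoothed per-class descriptor event probabilities,
#' stored in natural-log space. Fit with [fitNB()].
#'
#' @slot classes ordered class labels; the first is the tie-break winner.
#' @slot logPriors named numeric, natural-log class priors.
#' @slot logTheta classes x descriptors matrix of log event probabilities.
#' @slot alpha smoothing pseudo-count.
#' @slot descriptorNames descriptors the model was fit on.
#' @seealso [fitNB()], [predictProba()]
#' @export
setClass("NBMultinomialModel",
  representation(classes = "character", logPriors = "numeric",
                 logTheta = "matrix", alpha = "numeric",
                 descriptorNames = "character"))

setValidity("NBMultinomialModel", function(object) {
  msg <- character(0)
  if (abs(sum(exp(object@logPriors)) - 1) > 1e-12)
    msg <- c(msg, "priors must sum to 1")
  if (any(abs(rowSums(exp(object@logTheta)) - 1) > 1e-9))
    msg <- c(msg, "per-class event probabilities must sum to 1")
  if (!identical(rownames(object@logTheta), object@classes))
    msg <- c(msg, "logTheta rows must align with classes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NBMultinomialModel", function(object) {
  cat(sprintf(
    "NBMultinomialModel: %d classes (%s), %d descriptors, alpha = %g\n",
    length(object@classes), paste(object@classes, collapse = ", "),
    length(object@descriptorNames), object@alpha))
})

#' Pluggable classifier wrapper
#'
#' A uniform fit/predict-probability contract over the supported classifier
#' family. Create with [makeClassifier()], fit with [fitClassifier()].
#'
#' @slot name classifier name.
#' @slot params named list of classifier parameters.
#' @slot seed integer seed used by stochastic learners.
#' @slot fitted fitted state (NULL until [fitClassifier()] is called).
#' @export
setClass("PiRNAClassifier",
  representation(name = "character", params = "list", seed = "integer",
                 fitted = "ANY"))

setMethod("show", "PiRNAClassifier", function(object) {
  cat(sprintf("PiRNAClassifier '%s' (seed %d, %s)\n", object@name,
      object@seed, if (is.null(object@fitted)) "unfitted" else "fitted"))
})

#' Evaluation report
#'
#' Pooled confusion matrix plus the full metric suite (TPR, FPR, precision,
#' recall, F-measure, MCC, accuracy), per-class and class-size-weighted
#' variants, ROC and precision-recall curves with areas, and the provenance
#' (folds, seed, classifier) needed to reproduce the run.
#'
#' @slot confusion 2x2 integer matrix indexed (actual, predicted), positive
#'   class first.
#' @slot metrics named list of positive-class metrics (with `flags` marking
#'   zero-denominator ratios reported as 0).
#' @slot perClass data.frame of per-class metrics.
#' @slot weighted named list of class-size-weighted metrics.
#' @slot roc data.frame (threshold, fpr, tpr).
#' @slot pr data.frame (threshold, recall, precision).
#' @slot auc,auprc areas under the ROC and PR curves.
#' @slot folds,seed cross-validation provenance (0 folds = external set).
#' @slot classifier list describing the classifier used.
#' @slot scores positive-class probabilities for the evaluated instances.
#' @slot truth,predicted actual and predicted labels.
#' @seealso [crossValidate()], [metricsFromConfusion()]
#' @export
setClass("EvaluationReport",
  representation(confusion = "matrix", metrics = "list",
                 perClass = "data.frame", weighted = "list",
                 roc = "data.frame", pr = "data.frame",
                 auc = "numeric", auprc = "numeric",
                 folds = "integer", seed = "integer", classifier = "list",
                 scores = "numeric", truth = "character",
                 predicted = "character"))

setMethod("show", "EvaluationReport", function(object) {
  m <- object@metrics
  cat(sprintf("EvaluationReport (%s, k = %d, seed = %d)\n",
      object@classifier$name, object@folds, object@seed))
  cat("confusion (actual x predicted):\n")
  print(object@confusion)
  cat(sprintf(
    "accuracy %.3f | TPR %.3f FPR %.3f | precision %.3f F %.3f MCC %.3f\n",
    m$accuracy, m$tpr, m$fpr, m$precision, m$f_measure, m$mcc))
  cat(sprintf("AUC %.3f  AUPRC %.3f\n", object@auc, object@auprc))
})
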