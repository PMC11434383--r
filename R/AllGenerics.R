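#' Compute the 1020-descriptor representation
#'
#' Maps normalized RNA sequences to the canonical descriptor panel: the 12
#' global descriptors (length, per-nucleotide counts and frequencies, mean
#' base mass, hydrogen-bond capacity, mirror symmetry), overlapping 2-/3-/4-mer
#' counts over the full sequence, and the same motif counts restricted to the
#' first five ("5s") and last five ("5e") nucleotides. For sequences shorter
#' than five nucleotides the whole sequence serves as both window.
#'
#' @param x a single RNA sequence (character scalar) or a [PiRNASet-class].
#' @param schema a [DescriptorSchema-class]; defaults to [buildSchema()].
#' @param ... unused.
#' @return for a character scalar, a named numeric vector of length 1020; for
#'   a [PiRNASet-class], a [PiRNAFeatures-class] (descriptors x instances).
#' @examples
#' v <- featurize("AUCGAUCGAUCGAUCGAUCGAUCG")
#' v[c("N", "A/N", "AU", "5sAU")]
#' @export
setGeneric("featurize", function(x, schema = buildSchema(), ...)
  standardGeneric("featurize"))

#' Class-membership probabilities
#'
#' @param object a fitted model ([NBMultinomialModel-class] or fitted
#'   [PiRNAClassifier-class]).
#' @param newdata a [PiRNAFeatures-class], or an instances-by-descriptors
#'   numeric matrix / named numeric vector aligned to the model's descriptors.
#' @param ... unused.
#' @return numeric matrix, instances x classes, rows summing to 1.
#' @export
setGeneric("predictProba", function(object, newdata, ...)
  standardGeneric("predictProba"))

#' @rdname classLabels
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname featureMatrix
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Fit a classifier on a feature table
#'
#' @param classifier an unfitted [PiRNAClassifier-class] from
#'   [makeClassifier()].
#' @param features a [PiRNAFeatures-class] with both classes present.
#' @param ... unused.
#' @return the classifier with its fitted state attached.
#' @export
setGeneric("fitClassifier", function(classifier, features, ...)
  standardGeneric("fitClassifier"))

#' Class labels of a feature container or sequence set
#'
#' @param x a [PiRNAFeatures-class] or [PiRNASet-class].
#' @return character vector of labels.
#' @name classLabels
NULL

#' Instances-by-descriptors matrix
#'
#' Transposed view of the descriptors-by-instances assay, the orientation
#' classifiers consume. Row names are instance ids, column names descriptor
#' names.
#'
#' @param x a [PiRNAFeatures-class].
#' @return numeric matrix, instances x descriptors.
#' @name featureMatrix
NULL

setMethod("classLabels", "PiRNAFeatures", function(x) x$label)
setMethod("classLabels", "PiRNASet", function(x) x@labels)
setMethod("featureMatrix", "PiRNAFeatures",
          function(x) t(SummarizedExperiment::assay(x, "descriptors")))
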