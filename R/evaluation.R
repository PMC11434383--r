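#' Stratified fold assignment
#'
#' Each class's instances are shuffled (driven only by `seed`) and dealt
#' round-robin across the k folds, so within every class the fold sizes
#' differ by at most one.
#'
#' @param labels class label per instance.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return integer fold index (1..k) per instance.
#' @export
stratifiedFolds <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop(sprintf("k = %d exceeds the %d instances", k, n))
  set.seed(seed)
  fold <- integer(n)
  start <- 0L  # continue the deal across classes so total sizes stay even
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + start) %% k) + 1L
    start <- (start + length(idx)) %% k
  }
  fold
}

#' Build a confusion matrix
#'
#' @param truth actual labels.
#' @param predicted predicted labels.
#' @param classes class order; the first class is positive. Defaults to
#'   "selected" first.
#' @return 2x2 (or CxC) integer matrix indexed (actual, predicted).
#' @export
confusionMatrix <- function(truth, predicted,
                            classes = .orderClasses(truth)) {
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(actual = classes, predicted = classes))
  m
}

# Positive-class metric set from a 2x2 confusion matrix; positive = row/col 1.
.binaryMetrics <- function(cm) {
  TP <- cm[1, 1]; FN <- cm[1, 2]; FP <- cm[2, 1]; TN <- cm[2, 2]
  flags <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) { flags <<- c(flags, what); 0 } else num / den
  }
  tpr <- ratio(TP, TP + FN, "tpr")
  fpr <- ratio(FP, FP + TN, "fpr")
  precision <- ratio(TP, TP + FP, "precision")
  recall <- tpr
  f <- ratio(2 * precision * recall, precision + recall, "f_measure")
  mccDen <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- ratio(TP * TN - FP * FN, mccDen, "mcc")
  list(tpr = tpr, fpr = fpr, precision = precision, recall = recall,
       f_measure = f, mcc = mcc,
       accuracy = (TP + TN) / sum(cm), flags = flags)
}

#' Metric suite from a confusion matrix
#'
#' True/false positive rate, precision, recall, F-measure, Matthews
#' correlation coefficient and accuracy for the positive class ("selected",
#' the first row/column), plus per-class variants and class-size-weighted
#' averages. Ratios with a zero denominator are reported as 0 and flagged.
#'
#' @param cm 2x2 confusion matrix indexed (actual, predicted), positive class
#'   first, e.g. from [confusionMatrix()].
#' @return list with elements `positive` (positive-class metrics incl.
#'   `flags`), `perClass` (data.frame, one row per class treated as
#'   positive), and `weighted` (class-size-weighted averages).
#' @examples
#' cm <- matrix(c(6L, 1L, 1L, 6L), 2, byrow = TRUE,
#'              dimnames = list(actual = c("selected", "random"),
#'                              predicted = c("selected", "random")))
#' metricsFromConfusion(cm)$positive$mcc
#' @export
metricsFromConfusion <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  per <- lapply(seq_along(classes), function(i) {
    other <- setdiff(seq_along(classes), i)
    m <- matrix(c(cm[i, i], sum(cm[i, other]),
                  sum(cm[other, i]), sum(cm[other, other])),
                2, byrow = TRUE)
    .binaryMetrics(m)
  })
  perClass <- data.frame(
    class = classes,
    do.call(rbind, lapply(per, function(p)
      as.data.frame(p[c("tpr", "fpr", "precision", "recall", "f_measure",
                        "mcc")]))))
  support <- rowSums(cm) / sum(cm)
  weighted <- lapply(c("tpr", "fpr", "precision", "recall", "f_measure",
                       "mcc"),
                     function(nm) sum(support * perClass[[nm]]))
  names(weighted) <- c("tpr", "fpr", "precision", "recall", "f_measure",
                       "mcc")
  weighted$accuracy <- sum(diag(cm)) / sum(cm)
  list(positive = per[[1]], perClass = perClass, weighted = weighted)
}

#' ROC and precision-recall curves by threshold sweep
#'
#' Thresholds sweep the distinct scores from high to low (ties grouped, which
#' makes the trapezoidal ROC area equal the tie-corrected Mann-Whitney rank
#' statistic). The PR area uses step interpolation (the sum of precision
#' times the recall increment at each threshold).
#'
#' @param scores positive-class probabilities or scores.
#' @param labels actual labels; both classes must be present.
#' @param positive positive class label (default "selected").
#' @return list with `roc` (data.frame threshold/fpr/tpr, starting (0,0) and
#'   ending (1,1)), `pr` (data.frame threshold/recall/precision), `auc`, and
#'   `auprc`.
#' @examples
#' rocAndPr(c(0.9, 0.8, 0.4, 0.3), c("selected", "random", "selected",
#'          "random"))$auc  # 0.75
#' @export
rocAndPr <- function(scores, labels, positive = "selected") {
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have the same length")
  y <- labels == positive
  P <- sum(y); N <- sum(!y)
  if (P == 0 || N == 0)
    stop("both classes must be present to compute ROC/PR curves")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  ends <- which(!duplicated(s, fromLast = TRUE))  # last index per tie group
  cumtp <- cumsum(y)[ends]
  cumfp <- cumsum(!y)[ends]
  roc <- data.frame(threshold = c(Inf, s[ends]),
                    fpr = c(0, cumfp / N), tpr = c(0, cumtp / P))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  rec <- cumtp / P
  prec <- cumtp / (cumtp + cumfp)
  pr <- data.frame(threshold = s[ends], recall = rec, precision = prec)
  auprc <- sum(diff(c(0, rec)) * prec)
  list(roc = roc, pr = pr, auc = auc, auprc = auprc)
}

# Assemble a full EvaluationReport from pooled predictions.
.buildReport <- function(truth, predicted, scores, classes, folds, seed,
                         classifier) {
  cm <- confusionMatrix(truth, predicted, classes = classes)
  met <- metricsFromConfusion(cm)
  curves <- rocAndPr(scores, truth, positive = classes[1])
  new("EvaluationReport", confusion = cm, metrics = met$positive,
      perClass = met$perClass, weighted = met$weighted,
      roc = curves$roc, pr = curves$pr, auc = curves$auc,
      auprc = curves$auprc, folds = as.integer(folds),
      seed = as.integer(seed), classifier = classifier,
      scores = scores, truth = truth, predicted = predicted)
}

#' Stratified k-fold cross-validation
#'
#' Out-of-fold predictions from all folds are pooled into a single confusion
#' matrix and score set, from which the entire metric suite and the ROC/PR
#' curves are computed. Fully reproducible from (features, classifier, k,
#' seed).
#'
#' @param features a [PiRNAFeatures-class] with both classes present.
#' @param classifier a [PiRNAClassifier-class] from [makeClassifier()]
#'   (default: the package's multinomial naive Bayes).
#' @param k number of folds (default 10).
#' @param seed seed for the fold assignment (default 1).
#' @return an [EvaluationReport-class].
#' @export
crossValidate <- function(features,
                          classifier = makeClassifier("nb_multinomial"),
                          k = 10L, seed = 1L) {
  stopifnot(is(features, "PiRNAFeatures"))
  labels <- classLabels(features)
  classes <- .orderClasses(labels)
  if (length(classes) < 2L) stop("cross-validation requires both classes")
  fold <- stratifiedFolds(labels, k = k, seed = seed)
  n <- length(labels)
  predicted <- character(n)
  scores <- numeric(n)
  for (f in sort(unique(fold))) {
    test <- fold == f
    fit <- fitClassifier(classifier, features[, !test])
    p <- predictProba(fit, features[, test])
    predicted[test] <- classes[max.col(p[, classes, drop = FALSE],
                                       ties.method = "first")]
    scores[test] <- p[, classes[1]]
  }
  .buildReport(labels, predicted, scores, classes, folds = k, seed = seed,
               classifier = list(name = classifier@name,
                                 params = classifier@params,
                                 seed = classifier@seed))
}

#' Evaluate a fitted model on an external feature table
#'
#' @param model a fitted [PiRNAClassifier-class] or [NBMultinomialModel-class].
#' @param features a [PiRNAFeatures-class] with true labels for both classes.
#' @param seed recorded in the report (default 1).
#' @return an [EvaluationReport-class] with `folds = 0`.
#' @export
evaluateOn <- function(model, features, seed = 1L) {
  labels <- classLabels(features)
  classes <- if (is(model, "NBMultinomialModel")) model@classes else
    model@fitted$classes
  p <- predictProba(model, features)
  predicted <- classes[max.col(p[, classes, drop = FALSE],
                               ties.method = "first")]
  name <- if (is(model, "NBMultinomialModel")) "nb_multinomial" else
    model@name
  .buildReport(labels, predicted, p[, classes[1]], classes, folds = 0L,
               seed = seed, classifier = list(name = name))
}

#' Fraction of an independent set classified as disease-associated
#'
#' The independent-set "accuracy" protocol: the number of instances predicted
#' "selected" over the total evaluated. For a disease-associated input panel
#' this is the diagnostic accuracy; for an unrelated panel a low value
#' indicates selectivity.
#'
#' @param model a fitted [PiRNAClassifier-class] or [NBMultinomialModel-class].
#' @param features a [PiRNAFeatures-class] featurized on the model's selected
#'   descriptors (labels are ignored).
#' @param positive positive class label (default "selected").
#' @return fraction in \[0, 1\], with attributes `n_positive` and `n`.
#' @export
externalPositiveRate <- function(model, features, positive = "selected") {
  pred <- predict(model, features)
  rate <- mean(pred == positive)
  structure(rate, n_positive = sum(pred == positive), n = length(pred))
}

#' Export an evaluation report
#'
#' @param report an [EvaluationReport-class].
#' @param path JSON output path; with `tsv = TRUE` the ROC and PR points are
#'   written next to it as `<path>.roc.tsv` / `<path>.pr.tsv`.
#' @param tsv also write curve TSVs (default FALSE).
#' @return `path`, invisibly.
#' @export
writeReportJSON <- function(report, path, tsv = FALSE) {
  jsonlite::write_json(list(
    confusion = list(classes = rownames(report@confusion),
                     counts = apply(report@confusion, 1, as.list,
                                    simplify = FALSE)),
    metrics = report@metrics[setdiff(names(report@metrics), "flags")],
    flags = report@metrics$flags,
    weighted = report@weighted,
    auc = report@auc, auprc = report@auprc,
    folds = report@folds, seed = report@seed,
    classifier = report@classifier),
    path, auto_unbox = TRUE, digits = NA)
  if (tsv) {
    write.table(report@roc, paste0(path, ".roc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(report@pr, paste0(path, ".pr.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
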