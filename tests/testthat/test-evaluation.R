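test_that("stratified folds balance every class and are seed-reproducible", {
  labels <- rep(c("selected", "random"), each = 13)
  fold <- stratifiedFolds(labels, k = 10, seed = 1)
  expect_length(fold, 26L)
  expect_true(all(table(fold) %in% c(2L, 3L)))
  for (cl in c("selected", "random")) {
    per <- tabulate(fold[labels == cl], nbins = 10)
    expect_lte(max(per) - min(per), 1L)
  }
  expect_identical(stratifiedFolds(labels, k = 10, seed = 1), fold)
  expect_false(identical(stratifiedFolds(labels, k = 10, seed = 2), fold))

  # leave-one-out: every fold is a single instance
  loo <- stratifiedFolds(labels, k = 26, seed = 3)
  expect_identical(sort(tabulate(loo, 26)), rep(1L, 26))
  expect_error(stratifiedFolds(labels, k = 27, seed = 1), "exceeds")
})

test_that("confusion-matrix metrics match hand-computed values", {
  classes <- c("selected", "random")
  perfect <- matrix(c(7L, 0L, 0L, 7L), 2, byrow = TRUE,
                    dimnames = list(actual = classes, predicted = classes))
  m <- metricsFromConfusion(perfect)
  expect_equal(m$positive$tpr, 1)
  expect_equal(m$positive$fpr, 0)
  expect_equal(m$positive$mcc, 1)

  near <- matrix(c(6L, 1L, 1L, 6L), 2, byrow = TRUE,
                 dimnames = list(actual = classes, predicted = classes))
  mn <- metricsFromConfusion(near)$positive
  expect_equal(mn$tpr, 6 / 7, tolerance = 1e-9)
  expect_equal(mn$fpr, 1 / 7, tolerance = 1e-9)
  expect_equal(mn$mcc, 35 / 49, tolerance = 1e-9)   # (36-1)/sqrt(7^4)
  expect_equal(mn$f_measure, 6 / 7, tolerance = 1e-9)

  # everything predicted positive: TN = FN = 0, MCC flagged as 0
  allpos <- matrix(c(5L, 0L, 5L, 0L), 2, byrow = TRUE,
                   dimnames = list(actual = classes, predicted = classes))
  ma <- metricsFromConfusion(allpos)$positive
  expect_equal(ma$precision, 0.5)
  expect_equal(ma$fpr, 1)
  expect_equal(ma$mcc, 0)
  expect_true("mcc" %in% ma$flags)
  expect_error(metricsFromConfusion(matrix(0L, 2, 2,
    dimnames = list(actual = classes, predicted = classes))), "empty")
})

test_that("MCC is symmetric under a simultaneous class swap", {
  set.seed(91)
  for (i in 1:20) {
    cm <- matrix(sample(0:8, 4, replace = TRUE), 2,
                 dimnames = list(actual = c("selected", "random"),
                                 predicted = c("selected", "random")))
    if (sum(cm) == 0) next
    swapped <- cm[2:1, 2:1]
    dimnames(swapped) <- dimnames(cm)
    expect_equal(metricsFromConfusion(cm)$positive$mcc,
                 metricsFromConfusion(swapped)$positive$mcc,
                 tolerance = 1e-12)
  }
})

test_that("marginals of the confusion matrix equal the true class counts", {
  truth <- rep(c("selected", "random"), times = c(9, 5))
  pred <- sample(truth)
  cm <- confusionMatrix(truth, pred)
  expect_identical(as.integer(rowSums(cm)), c(9L, 5L))
  expect_identical(sum(cm), 14L)
})

test_that("ROC/PR sweep matches closed forms and the concordant-pair oracle", {
  r <- rocAndPr(c(0.9, 0.8, 0.4, 0.3),
                c("selected", "random", "selected", "random"))
  expect_equal(r$auc, 0.75)
  expect_identical(r$roc$fpr[1], 0)
  expect_identical(r$roc$tpr[1], 0)
  expect_identical(tail(r$roc$fpr, 1), 1)
  expect_identical(tail(r$roc$tpr, 1), 1)
  expect_true(!is.unsorted(r$roc$fpr))

  # perfectly ordered scores
  expect_equal(rocAndPr(c(0.9, 0.8, 0.2, 0.1),
                        c("selected", "selected", "random", "random"))$auc, 1)
  expect_equal(rocAndPr(c(0.9, 0.8, 0.2, 0.1),
                        c("selected", "selected", "random",
                          "random"))$auprc, 1)
  # all scores tied: chance AUC by tie correction
  expect_equal(rocAndPr(rep(0.5, 6),
                        rep(c("selected", "random"), 3))$auc, 0.5)

  set.seed(101)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    labels <- sample(c("selected", "random"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(rocAndPr(scores, labels)$auc, naiveAUC(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(rocAndPr(c(0.1, 0.9), c("selected", "selected")),
               "both classes")
})

test_that("trapezoid AUC agrees with an established ROC implementation", {
  set.seed(111)
  for (i in 1:10) {
    labels <- sample(c("selected", "random"), 30, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(stats::runif(30), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("random", "selected"),
      direction = "<", quiet = TRUE)))
    expect_equal(rocAndPr(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("cross-validation separates a separable table and chance on permuted labels", {
  # pipeline artifact: descriptor selection, then CV on the reduced table
  feats <- selectDescriptors(benchmarkDataset("separable", seed = 1))
  rep1 <- crossValidate(feats, k = 10, seed = 1)
  expect_equal(rep1@metrics$accuracy, 1)
  expect_equal(rep1@metrics$mcc, 1)
  expect_equal(rep1@auc, 1)
  expect_identical(sum(rep1@confusion), 26L)

  # identical invocation reproduces the report bit-for-bit
  rep2 <- crossValidate(feats, k = 10, seed = 1)
  expect_identical(rep1@confusion, rep2@confusion)
  expect_equal(rep1@scores, rep2@scores, tolerance = 0)

  # label permutation destroys the signal: accuracy within binomial bounds
  null <- benchmarkDataset("null", seed = 5)
  repNull <- crossValidate(null, k = 10, seed = 5)
  expect_gte(repNull@metrics$accuracy, 0.35)
  expect_lte(repNull@metrics$accuracy, 0.65)
})

test_that("external positive rate is the predicted-positive fraction", {
  model <- fitNB(toyFeatures(matrix(c(9, 0, 0, 9), 2, byrow = TRUE,
                                    dimnames = list(NULL, c("m1", "m2"))),
                             c("selected", "random")), alpha = 1)
  # 7 instances, 6 with the positive signature
  newmat <- rbind(matrix(rep(c(5, 0), 6), ncol = 2, byrow = TRUE),
                  c(0, 5))
  colnames(newmat) <- c("m1", "m2")
  newf <- toyFeatures(newmat, rep("unknown", 7))
  rate <- externalPositiveRate(model, newf)
  expect_equal(as.numeric(rate), 6 / 7, tolerance = 1e-12)
  expect_identical(attr(rate, "n_positive"), 6L)

  # none positive
  none <- toyFeatures(matrix(rep(c(0, 5), 4), ncol = 2, byrow = TRUE,
                             dimnames = list(NULL, c("m1", "m2"))),
                      rep("unknown", 4))
  expect_equal(as.numeric(externalPositiveRate(model, none)), 0)
})

test_that("evaluation reports serialize to JSON with curve TSVs", {
  feats <- selectDescriptors(benchmarkDataset("separable", seed = 2))
  rep1 <- crossValidate(feats, k = 5, seed = 2)
  path <- tempfile(fileext = ".json")
  writeReportJSON(rep1, path, tsv = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$metrics$accuracy, rep1@metrics$accuracy)
  expect_equal(j$folds, 5)
  roc <- read.delim(paste0(path, ".roc.tsv"))
  expect_identical(colnames(roc), c("threshold", "fpr", "tpr"))
})
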