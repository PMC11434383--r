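.CLASSIFIER_NAMES <- c("nb_multinomial", "random_forest", "mlp", "adaboost",
                       "decision_table_like")

#' Create a classifier under the uniform fit/predict-probability contract
#'
#' "nb_multinomial" is this package's own multinomial naive Bayes
#' ([fitNB()]). The others delegate to standard implementations: a random
#' forest (\pkg{randomForest}), a single-hidden-layer perceptron
#' (\pkg{nnet}), AdaBoost.M1 over decision stumps (\pkg{rpart} base
#' learners), and a depth-limited decision tree standing in for a decision
#' table. Stochastic learners are fully determined by `seed`.
#'
#' @param name one of "nb_multinomial", "random_forest", "mlp", "adaboost",
#'   "decision_table_like".
#' @param params named list of parameters (e.g. `alpha` for the naive Bayes,
#'   `ntree`, `size`, `decay`, `maxit`, `n_rounds`, `maxdepth`).
#' @param seed integer seed recorded in all reports.
#' @return an unfitted [PiRNAClassifier-class].
#' @examples
#' clf <- makeClassifier("nb_multinomial", params = list(alpha = 1))
#' @export
makeClassifier <- function(name, params = list(), seed = 1L) {
  if (!name %in% .CLASSIFIER_NAMES)
    stop("unknown classifier '", name, "'; supported: ",
         paste(.CLASSIFIER_NAMES, collapse = ", "))
  new("PiRNAClassifier", name = name, params = params,
      seed = as.integer(seed), fitted = NULL)
}

.param <- function(clf, key, default) {
  if (!is.null(clf@params[[key]])) clf@params[[key]] else default
}

# rpart needs syntactic column names; keep a stable V1..Vd mapping.
.safeFrame <- function(x) {
  df <- as.data.frame(x)
  colnames(df) <- paste0("V", seq_len(ncol(df)))
  df
}

# AdaBoost.M1 with depth-1 rpart stumps.
.fitAdaboost <- function(x, y, nRounds, seed) {
  set.seed(seed)
  df <- .safeFrame(x)
  n <- nrow(df)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  for (m in seq_len(nRounds)) {
    fit <- rpart::rpart(y ~ ., data = cbind(y = y, df), weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       minsplit = 2,
                                                       cp = -1, xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    a <- log((1 - err) / err)
    learners[[length(learners) + 1L]] <- fit
    alphas <- c(alphas, a)
    w <- w * exp(a * (pred != y))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(learners = learners, alphas = alphas, levels = levels(y))
}

.predictAdaboost <- function(model, x) {
  df <- .safeFrame(x)
  votes <- matrix(0, nrow(df), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (m in seq_along(model$learners)) {
    pred <- match(as.character(predict(model$learners[[m]], df,
                                       type = "class")), model$levels)
    idx <- cbind(seq_len(nrow(df)), pred)
    votes[idx] <- votes[idx] + model$alphas[m]
  }
  if (!length(model$learners))
    return(matrix(1 / ncol(votes), nrow(df), ncol(votes),
                  dimnames = dimnames(votes)))
  votes / pmax(rowSums(votes), .Machine$double.eps)
}

#' @rdname fitClassifier
#' @export
setMethod("fitClassifier", "PiRNAClassifier", function(classifier, features,
                                                       ...) {
  x <- featureMatrix(features)
  labels <- classLabels(features)
  classes <- .orderClasses(labels)
  if (length(classes) < 2L) stop("training data must contain both classes")
  y <- factor(labels, levels = classes)
  fitted <- switch(classifier@name,
    nb_multinomial = fitNB(features, alpha = .param(classifier, "alpha", 1)),
    random_forest = {
      set.seed(classifier@seed)
      randomForest::randomForest(x = x, y = y,
                                 ntree = .param(classifier, "ntree", 500L))
    },
    mlp = {
      set.seed(classifier@seed)
      nnet::nnet(x = x, y = stats::model.matrix(~ y - 1),
                 size = .param(classifier, "size", 4L),
                 decay = .param(classifier, "decay", 0.1),
                 maxit = .param(classifier, "maxit", 200L),
                 softmax = TRUE, trace = FALSE)
    },
    adaboost = .fitAdaboost(x, y, .param(classifier, "n_rounds", 50L),
                            classifier@seed),
    decision_table_like = {
      set.seed(classifier@seed)
      df <- .safeFrame(x)
      rpart::rpart(y ~ ., data = cbind(y = y, df), method = "class",
                   control = rpart::rpart.control(
                     maxdepth = .param(classifier, "maxdepth", 3L),
                     minsplit = 2, cp = 0.01, xval = 0))
    })
  classifier@fitted <- list(model = fitted, classes = classes,
                            descriptors = colnames(x))
  classifier
})

#' @rdname predictProba
#' @export
setMethod("predictProba", "PiRNAClassifier", function(object, newdata, ...) {
  if (is.null(object@fitted)) stop("classifier has not been fitted")
  st <- object@fitted
  if (is(newdata, "PiRNAFeatures")) newdata <- featureMatrix(newdata)
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list("query", names(newdata)))
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(st$descriptors, colnames(newdata))
    if (length(missing))
      stop("input is missing model descriptor(s): ",
           paste(missing, collapse = ", "))
    newdata <- newdata[, st$descriptors, drop = FALSE]
  }
  p <- switch(object@name,
    nb_multinomial = predictProba(st$model, newdata),
    random_forest = predict(st$model, newdata, type = "prob"),
    mlp = {
      pr <- predict(st$model, newdata)
      colnames(pr) <- st$classes
      pr
    },
    adaboost = .predictAdaboost(st$model, newdata),
    decision_table_like = predict(st$model, .safeFrame(newdata),
                                  type = "prob"))
  p <- p[, st$classes, drop = FALSE]
  rownames(p) <- rownames(newdata)
  p
})

#' Predicted labels from a fitted classifier
#'
#' @param object a fitted [PiRNAClassifier-class].
#' @param newdata a [PiRNAFeatures-class] or matrix aligned to the training
#'   descriptors.
#' @param ... unused.
#' @return character vector of predicted labels (ties go to the first class,
#'   i.e. "selected" when present).
#' @export
setMethod("predict", "PiRNAClassifier", function(object, newdata, ...) {
  p <- predictProba(object, newdata)
  object@fitted$classes[max.col(p, ties.method = "first")]
})
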