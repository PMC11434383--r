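# Canonical class ordering: the disease-associated class first (it is both
# the positive class and the deterministic tie-break winner), then the rest
# in sorted order.
.orderClasses <- function(labels) {
  u <- unique(labels)
  c(intersect(c("selected", "random"), u), sort(setdiff(u, c("selected",
                                                             "random"))))
}

#' Fit a multinomial naive Bayes model
#'
#' Descriptor values are treated as (possibly fractional) multinomial event
#' counts. Priors are class frequencies; the smoothed event probability of
#' descriptor i in class c is
#' \deqn{\theta_{ci} = \frac{\sum_{r \in c} x_{ri} + \alpha}
#'                          {\sum_{r \in c} \sum_j x_{rj} + \alpha d},}
#' with d the number of descriptors and \eqn{\alpha} the Laplace pseudo-count.
#' All computation downstream is in log space.
#'
#' @param features a [PiRNAFeatures-class] with two or more classes and
#'   non-negative values, typically the output of [selectDescriptors()].
#' @param alpha smoothing pseudo-count (default 1).
#' @return an [NBMultinomialModel-class].
#' @export
fitNB <- function(features, alpha = 1) {
  stopifnot(is(features, "PiRNAFeatures"))
  x <- featureMatrix(features)
  labels <- classLabels(features)
  if (alpha < 0) stop("alpha must be >= 0")
  neg <- which(colSums(x < 0) > 0)
  if (length(neg))
    stop("negative feature values in descriptor(s): ",
         paste(colnames(x)[neg], collapse = ", "))
  classes <- .orderClasses(labels)
  if (length(classes) < 2L)
    stop("model fitting requires at least two classes, got: ",
         paste(classes, collapse = ", "))
  d <- ncol(x)
  theta <- t(vapply(classes, function(cl) {
    rows <- x[labels == cl, , drop = FALSE]
    if (nrow(rows) == 0L) stop("class '", cl, "' has no instances")
    s <- colSums(rows)
    (s + alpha) / (sum(s) + alpha * d)
  }, numeric(d)))
  rownames(theta) <- classes
  colnames(theta) <- colnames(x)
  priors <- as.vector(table(factor(labels, levels = classes))) /
    length(labels)
  new("NBMultinomialModel", classes = classes,
      logPriors = setNames(log(priors), classes),
      logTheta = log(theta), alpha = alpha,
      descriptorNames = colnames(x))
}

# Align newdata (vector / matrix / PiRNAFeatures) to the model's descriptors,
# returning an instances x descriptors matrix.
.alignToModel <- function(object, newdata) {
  if (is(newdata, "PiRNAFeatures")) newdata <- featureMatrix(newdata)
  if (is.null(dim(newdata))) {
    nm <- names(newdata)
    newdata <- matrix(newdata, nrow = 1, dimnames = list("query", nm))
  }
  have <- colnames(newdata)
  want <- object@descriptorNames
  if (is.null(have)) {
    if (ncol(newdata) != length(want))
      stop("unnamed input with ", ncol(newdata), " descriptors; model needs ",
           length(want))
    colnames(newdata) <- want
    return(newdata)
  }
  missing <- setdiff(want, have)
  if (length(missing))
    stop("input is missing model descriptor(s): ",
         paste(missing, collapse = ", "))
  newdata[, want, drop = FALSE]
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "NBMultinomialModel", function(object, newdata, ...) {
  x <- .alignToModel(object, newdata)
  if (any(x < 0)) stop("descriptor values must be >= 0")
  logpost <- x %*% t(object@logTheta) +
    matrix(object@logPriors, nrow(x), length(object@classes), byrow = TRUE)
  m <- apply(logpost, 1, max)
  p <- exp(logpost - m)
  p <- p / rowSums(p)
  colnames(p) <- object@classes
  rownames(p) <- rownames(x)
  p
})

#' Predicted class labels
#'
#' Argmax of the posterior with a deterministic tie-break toward the first
#' class in the model's class order (the positive, disease-associated class
#' when present).
#'
#' @param object an [NBMultinomialModel-class].
#' @param newdata as for [predictProba()].
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
setMethod("predict", "NBMultinomialModel", function(object, newdata, ...) {
  p <- predictProba(object, newdata)
  object@classes[max.col(p, ties.method = "first")]
})

#' Serialize a fitted naive Bayes model to JSON
#'
#' @param model an [NBMultinomialModel-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeModelJSON <- function(model, path) {
  jsonlite::write_json(list(
    type = "nb_multinomial",
    classes = model@classes,
    log_priors = as.list(model@logPriors),
    log_theta = lapply(seq_along(model@classes),
                       function(i) unname(model@logTheta[i, ])),
    alpha = model@alpha,
    descriptor_names = model@descriptorNames,
    package_version = as.character(utils::packageVersion("piRNAdx"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [writeModelJSON()]
#'
#' @param path JSON path.
#' @return an [NBMultinomialModel-class].
#' @export
readModelJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- matrix(unlist(j$log_theta), nrow = length(j$classes), byrow = TRUE,
                  dimnames = list(j$classes, j$descriptor_names))
  new("NBMultinomialModel", classes = j$classes,
      logPriors = setNames(unlist(j$log_priors[j$classes]), j$classes),
      logTheta = theta, alpha = j$alpha,
      descriptorNames = j$descriptor_names)
}
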