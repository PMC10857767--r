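# Small feedforward NN classifier used inside the feature search and for
# final reporting, plus the confusion-matrix metrics. The network has one
# hidden layer (the configurations studied are 10 or 20 hidden units),
# uniform random initial weights, and softmax outputs trained by BFGS via
# nnet; training is deterministic given the spec seed.

#' Classifier specification
#'
#' @param hiddenSizes integer vector of hidden-layer widths; exactly one
#'   hidden layer is supported (e.g. `10` or `20`).
#' @param epochs maximum training iterations (default 1500; a reduced value
#'   such as 60-100 is the usual choice inside selection loops, with the
#'   full budget reserved for the final refit).
#' @param initRange half-width of the uniform random initializer for weights
#'   and biases (default 0.05).
#' @param seed integer RNG seed for weight initialization.
#' @param decay L2 weight decay passed to the optimizer.
#' @return a `ClassifierSpec` object (list).
#' @export
classifierSpec <- function(hiddenSizes = 10L, epochs = 1500L,
                           initRange = 0.05, seed = 1L, decay = 0) {
  stopifnot(all(hiddenSizes >= 1), epochs >= 1, initRange > 0)
  if (length(hiddenSizes) != 1L)
    stop("only a single hidden layer is supported; got ",
         length(hiddenSizes), " layers")
  structure(list(hiddenSizes = as.integer(hiddenSizes),
                 epochs = as.integer(epochs), initRange = initRange,
                 seed = as.integer(seed), decay = decay),
            class = "ClassifierSpec")
}

#' Train the feedforward classifier
#'
#' Fits a single-hidden-layer network with softmax outputs on standardized
#' features. Deterministic given `spec$seed` (or the `seed` override).
#'
#' @param spec a [classifierSpec()].
#' @param X numeric matrix `[n, p]` of (standardized) features.
#' @param y factor of class labels; every level must be present.
#' @param seed optional seed overriding `spec$seed` (used by the selection
#'   loop to derive per-(step, candidate) seeds).
#' @return a trained model handle for [evaluateClassifier()].
#' @export
trainClassifier <- function(spec, X, y, seed = spec$seed) {
  X <- as.matrix(X)
  y <- as.factor(y)
  stopifnot(nrow(X) == length(y), all(is.finite(X)))
  present <- table(y)
  if (any(present == 0) || nlevels(y) < 2)
    stop("every class must be present in the training labels; got counts: ",
         paste(sprintf("%s=%d", names(present), present), collapse = ", "))
  yInd <- stats::model.matrix(~ y - 1)
  colnames(yInd) <- levels(y)
  set.seed(seed)
  fit <- nnet::nnet(x = X, y = yInd, size = spec$hiddenSizes,
                    softmax = TRUE, rang = spec$initRange,
                    decay = spec$decay, maxit = spec$epochs,
                    trace = FALSE, MaxNWts = 100000L)
  structure(list(fit = fit, levels = levels(y), spec = spec, p = ncol(X)),
            class = "nuwsClassifier")
}

#' Predict class labels
#'
#' @param object a trained `nuwsClassifier`.
#' @param newdata numeric feature matrix with the training column count.
#' @param ... ignored.
#' @return factor of predicted labels.
#' @export
predict.nuwsClassifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("feature count mismatch: model expects ", object$p, ", got ",
         ncol(newdata))
  probs <- stats::predict(object$fit, newdata)
  factor(object$levels[max.col(probs, ties.method = "first")],
         levels = object$levels)
}

#' Metrics from a confusion matrix
#'
#' Computes accuracy, per-class recall/precision and, for binary problems
#' (positive class = second row/column), sensitivity, specificity and the
#' Matthews correlation coefficient. An MCC whose denominator contains a
#' zero factor is reported as 0 with the degenerate flag set.
#'
#' @param cm square numeric matrix, rows = truth, columns = prediction.
#' @return a [MetricsReport-class].
#' @export
metricsFromConfusion <- function(cm) {
  stopifnot(nrow(cm) == ncol(cm))
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  recall <- diag(cm) / rowSums(cm)
  precision <- diag(cm) / colSums(cm)
  perClass <- data.frame(class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
                         recall = as.numeric(recall),
                         precision = as.numeric(precision))
  sens <- spec <- mcc <- NA_real_
  degenerate <- FALSE
  if (nrow(cm) == 2L) {
    tn <- cm[1L, 1L]; fp <- cm[1L, 2L]; fn <- cm[2L, 1L]; tp <- cm[2L, 2L]
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    den <- c(tp + fp, tp + fn, tn + fp, tn + fn)
    if (any(den == 0)) {
      mcc <- 0
      degenerate <- TRUE
    } else {
      mcc <- (tp * tn - fp * fn) / sqrt(prod(den))
    }
  }
  new("MetricsReport", confusion = cm, accuracy = acc,
      sensitivity = sens, specificity = spec, mcc = mcc,
      perClass = perClass, degenerate = degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a trained classifier
#'
#' Predicts on a test split and derives all metrics from the confusion
#' matrix.
#'
#' @param model a trained `nuwsClassifier`.
#' @param X numeric feature matrix.
#' @param y factor of true labels.
#' @return a [MetricsReport-class].
#' @export
evaluateClassifier <- function(model, X, y) {
  y <- factor(y, levels = model$levels)
  if (nrow(as.matrix(X)) != length(y))
    stop("X has ", nrow(as.matrix(X)), " rows but y has ", length(y),
         " labels")
  pred <- predict(model, X)
  cm <- table(truth = y, prediction = pred)
  metricsFromConfusion(unclass(matrix(as.numeric(cm), nrow(cm),
                                      dimnames = dimnames(cm))))
}

#' Zero-rule baseline accuracy
#'
#' Attributes to every evaluated example the most frequent class of the
#' evaluated set, so its accuracy equals the majority-class proportion.
#'
#' @param yTrain training labels (unused by the rule; kept for the
#'   conventional baseline signature).
#' @param yTest labels of the evaluated set.
#' @return numeric accuracy in \[0, 1\].
#' @export
zeroRule <- function(yTrain, yTest) {
  stopifnot(length(yTest) >= 1)
  max(table(yTest)) / length(yTest)
}

#' Count trainable parameters of a fully connected network
#'
#' Sums `n_in * n_out + n_out` (weights + biases) over consecutive layer
#' pairs. A 16-20-6 network has 466 parameters, a 17-20-6 network 486.
#'
#' @param nInputs input dimension.
#' @param hiddenSizes integer vector of hidden-layer widths.
#' @param nOutputs number of output units.
#' @return integer parameter count.
#' @examples
#' countParameters(16, 20, 6)  # 466
#' @export
countParameters <- function(nInputs, hiddenSizes, nOutputs) {
  stopifnot(nInputs >= 1, all(hiddenSizes >= 1), nOutputs >= 1)
  sizes <- c(nInputs, hiddenSizes, nOutputs)
  total <- 0L
  for (i in seq_len(length(sizes) - 1L))
    total <- total + sizes[i] * sizes[i + 1L] + sizes[i + 1L]
  as.integer(total)
}

#' @describeIn confusion metrics-report confusion matrix
#' @export
setMethod("confusion", "MetricsReport", function(x) x@confusion)

#' @describeIn accuracy metrics-report accuracy
#' @export
setMethod("accuracy", "MetricsReport", function(x) x@accuracy)

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: accuracy %.4f", object@accuracy))
  if (!is.na(object@mcc))
    cat(sprintf(", sensitivity %.4f, specificity %.4f, MCC %.4f",
                object@sensitivity, object@specificity, object@mcc))
  cat("\n")
  print(object@confusion)
})
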