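# Base-learner registry. Every learner is wrapped so that:
#  - fit_learner(name, x, y, params, seed) returns a "base_learner" whose
#    class set is the FULL level set of y (even levels absent in x's rows);
#  - predict_learner(obj, x) returns an n x classes probability matrix whose
#    rows sum to 1, aligned on obj$classes;
#  - a single-class fit degrades to a constant predictor instead of erroring;
#  - all stochastic fits are reproducible from `seed`.

#' Names of the supported base learners
#'
#' Support vector machine, random forest, logistic regression,
#' k-nearest neighbours and multilayer perceptron.
#' @export
LEARNER_NAMES <- c("SVM", "RF", "LR", "KNN", "MLP")

#' Default base-learner hyperparameters
#'
#' RBF-kernel SVM with probability outputs, 100-tree random forest,
#' weight-decay-regularized (L2) logistic regression, k = 5 KNN and a
#' single-hidden-layer MLP. All overridable per learner, e.g. via
#' [bayes_optimize()].
#'
#' @return Named list of per-learner parameter lists.
#' @export
default_learner_params <- function() {
  list(
    SVM = list(kernel = "radial", cost = 1),
    RF  = list(ntree = 100),
    LR  = list(decay = 1e-4, maxit = 500),
    KNN = list(k = 5),
    MLP = list(size = 8, decay = 1e-3, maxit = 300)
  )
}

#' Fit one base learner
#'
#' @param name One of `"SVM"`, `"RF"`, `"LR"`, `"KNN"`, `"MLP"`.
#' @param x Numeric matrix of features.
#' @param y Factor of class labels (full level set kept).
#' @param params Hyperparameter list; defaults from
#'   [default_learner_params()].
#' @param seed Integer seed for the stochastic fits (RF, MLP).
#' @return A `base_learner` object.
#' @export
fit_learner <- function(name, x, y, params = NULL, seed = 1) {
  name <- match.arg(name, LEARNER_NAMES)
  x <- as.matrix(x)
  y <- if (is.factor(y)) y else factor(y)
  p <- utils::modifyList(default_learner_params()[[name]],
                         as.list(params %||% list()))
  classes <- levels(y)
  present <- unique(as.character(y))
  if (length(present) < 2) {
    return(constant_learner(present[1], classes))
  }
  yd <- droplevels(y)
  set.seed(stage_seed(seed, 0))
  fit <- switch(
    name,
    SVM = e1071::svm(x, yd, kernel = p$kernel, cost = p$cost,
                     gamma = p$gamma %||% (1 / ncol(x)),
                     probability = TRUE),
    RF = randomForest::randomForest(x, yd, ntree = p$ntree,
                                    mtry = p$mtry %||%
                                      max(1, floor(sqrt(ncol(x))))),
    LR = fit_multinom(x, yd, decay = p$decay, maxit = p$maxit),
    KNN = caret::knn3(x, yd, k = min(p$k, nrow(x))),
    MLP = fit_nnet(x, yd, size = p$size, decay = p$decay, maxit = p$maxit)
  )
  out <- list(name = name, fit = fit, classes = classes,
              fitted_levels = levels(yd), params = p)
  class(out) <- "base_learner"
  out
}

constant_learner <- function(class_label, classes) {
  out <- list(name = "CONST", fit = NULL, classes = classes,
              constant = class_label)
  class(out) <- c("constant_learner", "base_learner")
  out
}

fit_multinom <- function(x, y, decay, maxit) {
  df <- data.frame(.y = y, x, check.names = FALSE)
  nnet::multinom(.y ~ ., data = df, decay = decay, maxit = maxit,
                 trace = FALSE, MaxNWts = 1e5)
}

fit_nnet <- function(x, y, size, decay, maxit) {
  df <- data.frame(.y = y, x, check.names = FALSE)
  nnet::nnet(.y ~ ., data = df, size = size, decay = decay, maxit = maxit,
             trace = FALSE, MaxNWts = 1e5)
}

#' Class-probability predictions from a base learner
#'
#' @param object A `base_learner`.
#' @param x Numeric matrix of features.
#' @return n x classes probability matrix (columns = `object$classes`,
#'   rows sum to 1). Learners that cannot produce probabilities fall back
#'   to a one-hot encoding of their class prediction.
#' @export
predict_learner <- function(object, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  classes <- object$classes
  if (inherits(object, "constant_learner")) {
    return(one_hot(rep(object$constant, n), classes))
  }
  probs <- tryCatch(
    learner_probs(object, x),
    error = function(e) NULL
  )
  if (is.null(probs)) {
    cls <- as.character(predict_learner_class_raw(object, x))
    return(one_hot(cls, classes))
  }
  align_probs(probs, classes)
}

learner_probs <- function(object, x) {
  fit <- object$fit
  lv <- object$fitted_levels
  switch(
    object$name,
    SVM = {
      pr <- predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")
    },
    RF = predict(fit, x, type = "prob"),
    LR = {
      pr <- predict(fit, data.frame(x, check.names = FALSE), type = "probs")
      binary_to_matrix(pr, lv)
    },
    KNN = predict(fit, x, type = "prob"),
    MLP = {
      pr <- predict(fit, data.frame(x, check.names = FALSE), type = "raw")
      binary_to_matrix(pr, lv)
    }
  )
}

# nnet/multinom return a bare vector of P(second level) for 2-level factors.
binary_to_matrix <- function(pr, lv) {
  if (is.matrix(pr) && ncol(pr) > 1) return(pr)
  pr <- as.numeric(pr)
  m <- cbind(1 - pr, pr)
  colnames(m) <- lv
  m
}

predict_learner_class_raw <- function(object, x) {
  fit <- object$fit
  switch(
    object$name,
    LR = predict(fit, data.frame(x, check.names = FALSE)),
    MLP = predict(fit, data.frame(x, check.names = FALSE), type = "class"),
    KNN = predict(fit, x, type = "class"),
    predict(fit, x)
  )
}

one_hot <- function(cls, classes) {
  m <- matrix(0, length(cls), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(cls), match(cls, classes))] <- 1
  m
}

# Re-align a probability matrix onto the full class set, zero-filling
# classes the learner never saw, and renormalize rows.
align_probs <- function(probs, classes) {
  probs <- as.matrix(probs)
  out <- matrix(0, nrow(probs), length(classes),
                dimnames = list(rownames(probs), classes))
  common <- intersect(colnames(probs), classes)
  out[, common] <- probs[, common, drop = FALSE]
  rs <- rowSums(out)
  rs[rs == 0] <- 1
  out / rs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# argmax with lowest-index tie-break
argmax_class <- function(probs) {
  classes <- colnames(probs)
  classes[apply(probs, 1, which.max)]
}
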