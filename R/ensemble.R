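#' Fit a plain soft-voting ensemble
#'
#' Fits each named base learner on the full training data and combines
#' them at prediction time by unweighted averaging of class-probability
#' vectors ("soft" voting) or by majority vote over class predictions
#' ("hard"). This is the non-hybrid baseline every hybrid variant is
#' benchmarked against.
#'
#' @param x Numeric matrix (or `feature_table`) of training features.
#' @param y Class labels.
#' @param combination Character vector of learner names, subset of
#'   SVM/RF/LR/KNN/MLP, size 1-5.
#' @param learner_params Per-learner hyperparameter lists; defaults from
#'   [default_learner_params()].
#' @param voting `"soft"` (default) or `"hard"`.
#' @param seed Integer seed.
#' @return A `softvote_ensemble`.
#' @export
fit_softvote <- function(x, y, combination, learner_params = NULL,
                         voting = c("soft", "hard"), seed = 1) {
  voting <- match.arg(voting)
  combination <- check_combination(combination)
  xm <- ft_values(x)
  y <- if (is.factor(y)) y else factor(y)
  learners <- lapply(seq_along(combination), function(i) {
    nm <- combination[i]
    fit_learner(nm, xm, y, params = (learner_params %||% list())[[nm]],
                seed = stage_seed(seed, 100 + i))
  })
  names(learners) <- combination
  out <- list(learners = learners, combination = combination,
              voting = voting, classes = levels(y), seed = seed)
  class(out) <- "softvote_ensemble"
  out
}

check_combination <- function(combination) {
  combination <- as.character(combination)
  if (length(combination) < 1) stop("ensemble combination must be non-empty")
  bad <- setdiff(combination, LEARNER_NAMES)
  if (length(bad)) {
    stop("unknown learner name(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(LEARNER_NAMES, collapse = ", "), ")")
  }
  combination
}

# Shared vote combiner: mean of aligned probability matrices (soft) or
# one-hot majority (hard). Ties resolve to the lowest class index.
combine_votes <- function(learners, x, classes, voting) {
  mats <- lapply(learners, function(l) {
    p <- predict_learner(l, x)
    if (voting == "hard") one_hot(argmax_class(p), classes) else p
  })
  probs <- Reduce(`+`, mats) / length(mats)
  rs <- rowSums(probs)
  rs[rs == 0] <- 1
  probs / rs
}

#' Predict from a plain soft-voting ensemble
#'
#' @param object A `softvote_ensemble`.
#' @param newdata Feature matrix or `feature_table`.
#' @param type `"class"` (default), `"prob"`, or `"full"` (both).
#' @param ... Unused.
#' @return Class vector, probability matrix, or a list of both.
#' @export
predict.softvote_ensemble <- function(object, newdata,
                                      type = c("class", "prob", "full"),
                                      ...) {
  type <- match.arg(type)
  xm <- ft_values(newdata)
  probs <- combine_votes(object$learners, xm, object$classes, object$voting)
  cls <- argmax_class(probs)
  switch(type,
         class = cls,
         prob = probs,
         full = list(class = cls, prob = probs))
}

#' Enumerate learner combinations of a given size
#'
#' All unordered subsets of the given arity, in deterministic
#' (combn) order, named like benchmark rows ("SVM-RF", ...).
#'
#' @param learners Character vector of learner names.
#' @param arity Subset size, 1..length(learners).
#' @return Named list of character vectors.
#' @export
enumerate_combinations <- function(learners = LEARNER_NAMES, arity) {
  if (arity < 1 || arity > length(learners)) {
    stop("arity must be between 1 and ", length(learners))
  }
  combos <- combn(learners, arity, simplify = FALSE)
  names(combos) <- vapply(combos, paste, character(1), collapse = "-")
  combos
}
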