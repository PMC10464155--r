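#' Define a hyperparameter search space
#'
#' Each dimension is a list with `type` in `"real"`, `"logreal"`,
#' `"int"` or `"cat"`, plus `lower`/`upper` bounds (finite, lower <
#' upper) or a `values` set for categoricals.
#'
#' @param ... Named dimension definitions, e.g.
#'   `cost = list(type = "logreal", lower = 1e-2, upper = 1e2)`.
#' @return A `search_space`.
#' @export
search_space <- function(...) {
  dims <- list(...)
  if (!length(dims)) stop("search space must have at least one dimension")
  if (is.null(names(dims)) || any(!nzchar(names(dims)))) {
    stop("every search-space dimension must be named")
  }
  for (nm in names(dims)) {
    d <- dims[[nm]]
    if (!d$type %in% c("real", "logreal", "int", "cat")) {
      stop("dimension '", nm, "': unknown type '", d$type, "'")
    }
    if (d$type == "cat") {
      if (length(d$values) < 1) stop("dimension '", nm, "': empty value set")
    } else {
      if (!is.finite(d$lower) || !is.finite(d$upper) || d$lower >= d$upper) {
        stop("dimension '", nm, "': bounds must be finite with lower < upper")
      }
    }
  }
  class(dims) <- "search_space"
  dims
}

#' Default per-learner search spaces
#'
#' SVM: cost on a log scale in [1e-2, 1e2] and kernel in \{radial,
#' linear\}; RF: 50-300 trees; LR: decay on a log scale; KNN: k in
#' [1, 15]; MLP: 8-128 hidden units.
#'
#' @param name Learner name.
#' @return A [search_space()].
#' @export
default_search_space <- function(name) {
  name <- match.arg(name, LEARNER_NAMES)
  switch(
    name,
    SVM = search_space(cost = list(type = "logreal", lower = 1e-2, upper = 1e2),
                       kernel = list(type = "cat",
                                     values = c("radial", "linear"))),
    RF = search_space(ntree = list(type = "int", lower = 50, upper = 300)),
    LR = search_space(decay = list(type = "logreal", lower = 1e-6, upper = 1)),
    KNN = search_space(k = list(type = "int", lower = 1, upper = 15)),
    MLP = search_space(size = list(type = "int", lower = 8, upper = 128))
  )
}

# --- unit-cube encoding -----------------------------------------------------

space_dim <- function(space) length(space)

# decode a row of unit-cube coordinates into a named parameter list
decode_point <- function(u, space) {
  out <- list()
  for (i in seq_along(space)) {
    d <- space[[i]]
    out[[names(space)[i]]] <- switch(
      d$type,
      real = d$lower + u[i] * (d$upper - d$lower),
      logreal = exp(log(d$lower) + u[i] * (log(d$upper) - log(d$lower))),
      int = as.integer(round(d$lower + u[i] * (d$upper - d$lower))),
      cat = d$values[[pmin(length(d$values),
                           1 + floor(u[i] * length(d$values)))]]
    )
  }
  out
}

# --- Gaussian-process surrogate --------------------------------------------

# Squared-exponential kernel on unit-cube coordinates; fixed lengthscale
# (0.25 per dimension) and a small nugget keep the surrogate stable
# without hyperparameter fitting of its own.
gp_kernel <- function(A, B, lengthscale = 0.25) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * lengthscale^2))
}

gp_posterior <- function(X, y, Xnew, noise = 1e-6) {
  mu0 <- mean(y)
  s2 <- max(var(y), 1e-12)
  K <- s2 * gp_kernel(X, X) + diag(noise + 1e-8, nrow(X))
  Ks <- s2 * gp_kernel(Xnew, X)
  alpha <- solve(K, y - mu0)
  mean_post <- mu0 + Ks %*% alpha
  v <- solve(K, t(Ks))
  var_post <- pmax(s2 - rowSums(Ks * t(v)), 1e-12)
  list(mean = as.numeric(mean_post), sd = sqrt(var_post))
}

expected_improvement <- function(mu, sd, best) {
  imp <- mu - best
  z <- imp / sd
  ei <- imp * pnorm(z) + sd * stats::dnorm(z)
  ei[sd < 1e-12] <- 0
  ei
}

#' Maximize a black-box objective with GP-based Bayesian optimization
#'
#' Sequential model-based optimization: a Latin-hypercube initial design,
#' then a Gaussian-process surrogate (squared-exponential kernel) with
#' expected-improvement acquisition over a random candidate pool. Fully
#' deterministic given the seed.
#'
#' @param fn Objective `function(params) -> numeric` to maximize, where
#'   `params` is a named list decoded from the space.
#' @param space A [search_space()].
#' @param budget Total number of objective evaluations, >= 1.
#' @param seed Integer seed.
#' @param n_candidates Size of the acquisition candidate pool; default 500.
#' @return A `tuning_result` list: `best_params`, `best_value`, `history`
#'   (data frame of decoded parameters and scores, `budget` rows).
#' @export
bo_maximize <- function(fn, space, budget = 25, seed = 1,
                        n_candidates = 500) {
  stopifnot(inherits(space, "search_space"), budget >= 1)
  d <- space_dim(space)
  set.seed(stage_seed(seed, 0))
  n_init <- min(budget, max(3, d + 2))
  U <- lhs::randomLHS(n_init, d)
  scores <- numeric(0)
  params_list <- list()
  evaluate <- function(u) {
    p <- decode_point(u, space)
    params_list[[length(params_list) + 1]] <<- p
    scores <<- c(scores, as.numeric(fn(p)))
  }
  for (i in seq_len(n_init)) evaluate(U[i, , drop = TRUE])
  while (length(scores) < budget) {
    cand <- matrix(runif(n_candidates * d), n_candidates, d)
    post <- gp_posterior(U, scores, cand)
    ei <- expected_improvement(post$mean, post$sd, max(scores))
    u_next <- cand[which.max(ei), , drop = TRUE]
    U <- rbind(U, u_next)
    evaluate(u_next)
  }
  best <- which.max(scores)
  history <- cbind(
    do.call(rbind, lapply(params_list, function(p)
      as.data.frame(p, stringsAsFactors = FALSE))),
    score = scores)
  out <- list(best_params = params_list[[best]],
              best_value = scores[best],
              history = history)
  class(out) <- "tuning_result"
  out
}

#' Tune a base learner by Bayesian optimization of CV accuracy
#'
#' The objective is mean 5-fold cross-validated accuracy of the learner on
#' the given data; the folds are fixed across all evaluations so
#' configurations are compared on identical splits.
#'
#' @param name Learner name (SVM/RF/LR/KNN/MLP).
#' @param x Feature matrix or `feature_table`.
#' @param y Class labels.
#' @param space A [search_space()]; default [default_search_space()] for
#'   the learner.
#' @param budget Objective evaluations; default 25.
#' @param folds CV fold count; default 5.
#' @param seed Integer seed.
#' @return A `tuning_result` (see [bo_maximize()]), with the extra field
#'   `cv_accuracy` = `best_value`.
#' @export
bayes_optimize <- function(name, x, y, space = default_search_space(name),
                           budget = 25, folds = 5, seed = 1) {
  name <- match.arg(name, LEARNER_NAMES)
  xm <- ft_values(x)
  y <- if (is.factor(y)) y else factor(y)
  plan <- kfold_split(nrow(xm), k = folds, seed = stage_seed(seed, 11))
  objective <- function(params) {
    cv_accuracy(name, xm, y, params, plan, seed)
  }
  res <- bo_maximize(objective, space, budget = budget,
                     seed = stage_seed(seed, 13))
  res$cv_accuracy <- res$best_value
  res
}

#' Mean cross-validated accuracy of one learner configuration
#'
#' @param name Learner name.
#' @param x Feature matrix.
#' @param y Class labels.
#' @param params Hyperparameter list.
#' @param plan A `split_plan` from [kfold_split()] (fixed folds).
#' @param seed Integer seed for the per-fold fits.
#' @return Mean accuracy over the folds.
#' @export
cv_accuracy <- function(name, x, y, params, plan, seed = 1) {
  xm <- ft_values(x)
  y <- if (is.factor(y)) y else factor(y)
  accs <- vapply(seq_along(plan$folds), function(f) {
    test <- plan$folds[[f]]
    train <- setdiff(seq_len(nrow(xm)), test)
    fit <- fit_learner(name, xm[train, , drop = FALSE], y[train],
                       params = params, seed = stage_seed(seed, 200 + f))
    probs <- predict_learner(fit, xm[test, , drop = FALSE])
    mean(argmax_class(probs) == as.character(y[test]))
  }, numeric(1))
  mean(accs)
}
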