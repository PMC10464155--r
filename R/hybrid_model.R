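#' Hybrid model configuration
#'
#' Collects the tunable structure of the five-phase hybrid classifier.
#'
#' @param cluster_range Integer interval `c(k_lo, k_hi)` searched for the
#'   number of probability clusters; default `c(2, 8)`. `c(1, 1)` disables
#'   clustering and makes the hybrid equivalent to a plain soft-voting
#'   ensemble.
#' @param combination Base learners for the per-cluster ensembles (subset
#'   of SVM/RF/LR/KNN/MLP, size 1-5).
#' @param min_cluster_size Clusters smaller than this are merged into the
#'   nearest-centroid cluster before any per-cluster learner is fitted;
#'   default 5 so every learner has a fittable sample count.
#' @param probability_source `"in_sample"` (default: the logistic model is
#'   fitted on all training rows and scores the same rows, matching the
#'   sequential phase description) or `"out_of_fold"` (5-fold cross-fitted
#'   probabilities, which avoids scoring rows the model saw).
#' @param voting Phase-5 combiner: `"soft"` (mean of probability vectors,
#'   default) or `"hard"` (majority).
#' @param learner_params Optional per-learner hyperparameter overrides.
#' @param bridge Bridge SVM hyperparameters (kernel, cost).
#' @param lr Phase-2 logistic-regression hyperparameters (decay, maxit).
#' @param kmeans_nstart Random restarts per k-means run; default 10.
#' @param seed Integer seed from which every stochastic stage derives its
#'   own seed.
#' @return A `hybrid_config` list.
#' @export
hybrid_config <- function(cluster_range = c(2, 8),
                          combination = c("RF", "LR", "KNN", "MLP"),
                          min_cluster_size = 5,
                          probability_source = c("in_sample", "out_of_fold"),
                          voting = c("soft", "hard"),
                          learner_params = NULL,
                          bridge = list(kernel = "radial", cost = 1),
                          lr = list(decay = 1e-4, maxit = 500),
                          kmeans_nstart = 10,
                          seed = 1) {
  probability_source <- match.arg(probability_source)
  voting <- match.arg(voting)
  cluster_range <- as.integer(cluster_range)
  if (length(cluster_range) != 2 || cluster_range[1] < 1 ||
      cluster_range[1] > cluster_range[2]) {
    stop("cluster_range must be c(k_lo, k_hi) with 1 <= k_lo <= k_hi")
  }
  combination <- check_combination(combination)
  out <- list(cluster_range = cluster_range, combination = combination,
              min_cluster_size = as.integer(min_cluster_size),
              probability_source = probability_source, voting = voting,
              learner_params = learner_params, bridge = bridge, lr = lr,
              kmeans_nstart = as.integer(kmeans_nstart),
              seed = as.integer(seed))
  class(out) <- "hybrid_config"
  out
}

#' Phase 2: per-sample class probabilities from logistic regression
#'
#' Fits a (weight-decay regularized) multinomial logistic model and scores
#' each training sample, yielding the probability vectors whose clustering
#' defines the augmented labels.
#'
#' @param x Feature matrix or `feature_table` (preprocessed).
#' @param y Class labels (>= 2 classes).
#' @param source `"in_sample"` (fit on all rows, score the same rows) or
#'   `"out_of_fold"` (5-fold cross-fitted scores).
#' @param folds Fold count for `out_of_fold`; default 5.
#' @param lr Logistic hyperparameters (decay, maxit).
#' @param seed Integer seed (used for the fold split).
#' @return n x classes probability matrix; rows sum to 1.
#' @export
compute_class_probabilities <- function(x, y,
                                        source = c("in_sample", "out_of_fold"),
                                        folds = 5, lr = list(), seed = 1) {
  source <- match.arg(source)
  xm <- ft_values(x)
  y <- if (is.factor(y)) y else factor(y)
  if (nlevels(droplevels(y)) < 2) {
    stop("class probabilities require at least 2 classes")
  }
  lr <- utils::modifyList(list(decay = 1e-4, maxit = 500), lr)
  if (source == "in_sample") {
    fit <- fit_multinom(xm, droplevels(y), decay = lr$decay, maxit = lr$maxit)
    pr <- predict(fit, data.frame(xm, check.names = FALSE), type = "probs")
    P <- align_probs(binary_to_matrix(pr, levels(droplevels(y))), levels(y))
  } else {
    plan <- kfold_split(nrow(xm), k = folds, seed = stage_seed(seed, 7))
    P <- matrix(NA_real_, nrow(xm), nlevels(y),
                dimnames = list(rownames(xm), levels(y)))
    for (f in seq_along(plan$folds)) {
      test <- plan$folds[[f]]
      train <- setdiff(seq_len(nrow(xm)), test)
      ytr <- droplevels(y[train])
      if (nlevels(ytr) < 2) {
        P[test, ] <- 1 / nlevels(y)
        next
      }
      fit <- fit_multinom(xm[train, , drop = FALSE], ytr,
                          decay = lr$decay, maxit = lr$maxit)
      pr <- predict(fit, data.frame(xm[test, , drop = FALSE],
                                    check.names = FALSE), type = "probs")
      P[test, ] <- align_probs(binary_to_matrix(pr, levels(ytr)), levels(y))
    }
  }
  rownames(P) <- rownames(xm)
  P
}

#' Phase 3: choose the number of probability clusters
#'
#' Runs k-means (multiple random restarts, fixed seed) for each candidate k
#' and keeps the k with the highest mean silhouette width; ties go to the
#' smaller k. A single-valued range skips selection. k = 1 (no silhouette
#' defined) is only legal as the degenerate range `c(1, 1)`.
#'
#' @param probabilities n x classes probability matrix (Phase-2 output).
#' @param cluster_range Integer interval `c(k_lo, k_hi)`.
#' @param nstart k-means restarts; default 10.
#' @param seed Integer seed.
#' @return List with `n_clusters`, `assignments` (integer vector),
#'   `centers`, and `silhouette` (named mean widths per candidate k).
#' @export
select_cluster_count <- function(probabilities, cluster_range = c(2, 8),
                                 nstart = 10, seed = 1) {
  P <- as.matrix(probabilities)
  n <- nrow(P)
  if (n < 2) stop("clustering requires at least 2 samples")
  k_lo <- as.integer(cluster_range[1])
  k_hi <- as.integer(cluster_range[2])
  if (k_hi >= n) {
    warning("cluster_range upper bound ", k_hi, " >= sample count ", n,
            "; truncated to ", n - 1L)
    k_hi <- n - 1L
    k_lo <- min(k_lo, k_hi)
  }
  if (k_lo == 1 && k_hi == 1) {
    return(list(n_clusters = 1L, assignments = rep(1L, n),
                centers = matrix(colMeans(P), 1,
                                 dimnames = list(NULL, colnames(P))),
                silhouette = NULL))
  }
  candidates <- seq.int(max(2L, k_lo), k_hi)
  fits <- list()
  sil <- setNames(rep(NA_real_, length(candidates)), candidates)
  D <- stats::dist(P)
  for (i in seq_along(candidates)) {
    k <- candidates[i]
    set.seed(stage_seed(seed, 20 + k))
    km <- kmeans(P, centers = k, nstart = nstart, iter.max = 50)
    fits[[i]] <- km
    if (length(candidates) > 1) {
      sw <- cluster::silhouette(km$cluster, D)
      sil[i] <- mean(sw[, "sil_width"])
    }
  }
  best <- if (length(candidates) == 1) 1L else {
    # strict > keeps the smaller k on ties
    which.max(round(sil, 12))
  }
  km <- fits[[best]]
  list(n_clusters = candidates[best],
       assignments = as.integer(km$cluster),
       centers = km$centers,
       silhouette = if (length(candidates) > 1) sil else NULL)
}

#' Phase 3-4: combine original labels with cluster identities
#'
#' Encodes each (original class, cluster id) pair observed in training as a
#' dense composite code. The codec is invertible: every code maps back to
#' exactly one pair.
#'
#' @param labels Original class labels.
#' @param assignments Integer cluster ids, same length.
#' @return List with `codes` (factor of composite codes) and `codec`
#'   (data frame code / class / cluster).
#' @export
augment_labels <- function(labels, assignments) {
  if (length(labels) != length(assignments)) {
    stop("labels and assignments must have equal length")
  }
  y <- as.character(labels)
  pairs <- unique(data.frame(class = y, cluster = as.integer(assignments),
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$class, pairs$cluster), , drop = FALSE]
  pairs$code <- paste0(pairs$class, "@", pairs$cluster)
  codes <- factor(paste0(y, "@", as.integer(assignments)),
                  levels = pairs$code)
  list(codes = codes,
       codec = data.frame(code = pairs$code, class = pairs$class,
                          cluster = pairs$cluster,
                          stringsAsFactors = FALSE))
}

#' Phase 4: fit the SVM bridge on composite labels
#'
#' The bridge carries both class and routing information across the
#' train/test boundary: predicting a composite code for a test sample
#' simultaneously assigns it a cluster (used to pick the Phase-5 ensemble).
#' A single composite class degrades to a constant predictor.
#'
#' @param x Feature matrix or `feature_table`.
#' @param codes Factor of composite codes ([augment_labels()]).
#' @param params SVM hyperparameters (kernel, cost).
#' @param seed Integer seed.
#' @return A `bridge_model`.
#' @export
fit_bridge <- function(x, codes, params = list(), seed = 1) {
  xm <- ft_values(x)
  codes <- droplevels(factor(codes))
  p <- utils::modifyList(list(kernel = "radial", cost = 1), as.list(params))
  if (nlevels(codes) < 2) {
    out <- list(fit = NULL, constant = levels(codes)[1],
                levels = levels(codes))
  } else {
    set.seed(stage_seed(seed, 0))
    fit <- e1071::svm(xm, codes, kernel = p$kernel, cost = p$cost,
                      gamma = p$gamma %||% (1 / ncol(xm)))
    out <- list(fit = fit, constant = NULL, levels = levels(codes))
  }
  class(out) <- "bridge_model"
  out
}

#' @export
predict.bridge_model <- function(object, newdata, ...) {
  xm <- ft_values(newdata)
  if (!is.null(object$constant)) {
    return(factor(rep(object$constant, nrow(xm)), levels = object$levels))
  }
  predict(object$fit, xm)
}

# Merge clusters smaller than min_size into the nearest-centroid surviving
# cluster, by Euclidean distance in the clustering space.
merge_small_clusters <- function(space, assignments, min_size) {
  assignments <- as.integer(assignments)
  repeat {
    sizes <- table(assignments)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || length(sizes) <= 1) break
    # merge the smallest first
    victim <- small[which.min(sizes[small])]
    centers <- do.call(rbind, lapply(names(sizes), function(cl) {
      colMeans(space[assignments == as.integer(cl), , drop = FALSE])
    }))
    rownames(centers) <- names(sizes)
    d <- sqrt(rowSums(sweep(centers, 2, centers[victim, ])^2))
    d[victim] <- Inf
    target <- names(which.min(d))
    assignments[assignments == as.integer(victim)] <- as.integer(target)
  }
  assignments
}

#' Phase 5: fit per-cluster ensembles
#'
#' Fits every learner of the combination independently on each cluster's
#' rows. Clusters below `min_cluster_size` are first merged into the
#' nearest-centroid cluster; a cluster containing a single class gets a
#' constant predictor for that class.
#'
#' @param x Feature matrix or `feature_table`.
#' @param y Class labels.
#' @param assignments Integer cluster ids per training row.
#' @param combination Learner names (non-empty).
#' @param min_cluster_size Merge threshold; default 5.
#' @param learner_params Optional per-learner overrides.
#' @param seed Integer seed.
#' @param space Matrix in which cluster centroids are computed for the
#'   merge rule; defaults to `x` (the hybrid passes the probability
#'   matrix, i.e. the space the clusters were formed in).
#' @return List with `ensembles` (cluster id -> list of `base_learner`),
#'   `assignments` (post-merge), and `classes`.
#' @export
fit_cluster_ensembles <- function(x, y, assignments, combination,
                                  min_cluster_size = 5,
                                  learner_params = NULL, seed = 1,
                                  space = NULL) {
  combination <- check_combination(combination)
  xm <- ft_values(x)
  y <- if (is.factor(y)) y else factor(y)
  if (is.null(space)) space <- xm
  assignments <- merge_small_clusters(as.matrix(space),
                                      assignments, min_cluster_size)
  ensembles <- lapply(sort(unique(assignments)), function(cl) {
    rows <- which(assignments == cl)
    fits <- lapply(seq_along(combination), function(i) {
      nm <- combination[i]
      fit_learner(nm, xm[rows, , drop = FALSE], y[rows],
                  params = (learner_params %||% list())[[nm]],
                  seed = stage_seed(seed, 100 + i))
    })
    names(fits) <- combination
    fits
  })
  names(ensembles) <- as.character(sort(unique(assignments)))
  list(ensembles = ensembles, assignments = assignments,
       classes = levels(y))
}

#' Fit the hybrid classifier core (Phases 2-5) on preprocessed features
#'
#' @param x Feature matrix or `feature_table` (already featurized,
#'   normalized and projected).
#' @param y Class labels (>= 2 classes).
#' @param config A [hybrid_config()].
#' @return A `hybrid_core` model.
#' @export
fit_hybrid_core <- function(x, y, config = hybrid_config()) {
  stopifnot(inherits(config, "hybrid_config"))
  xm <- ft_values(x)
  y <- if (is.factor(y)) y else factor(y)
  if (nlevels(droplevels(y)) < 2) stop("hybrid fit requires >= 2 classes")
  seed <- config$seed
  P <- compute_class_probabilities(xm, y, source = config$probability_source,
                                   lr = config$lr,
                                   seed = stage_seed(seed, 1))
  sel <- select_cluster_count(P, cluster_range = config$cluster_range,
                              nstart = config$kmeans_nstart,
                              seed = stage_seed(seed, 2))
  ens <- fit_cluster_ensembles(xm, y, sel$assignments, config$combination,
                               min_cluster_size = config$min_cluster_size,
                               learner_params = config$learner_params,
                               seed = seed, space = P)
  aug <- augment_labels(y, ens$assignments)
  bridge <- fit_bridge(xm, aug$codes, params = config$bridge,
                       seed = stage_seed(seed, 3))
  out <- list(config = config, classes = levels(y),
              n_clusters = length(ens$ensembles),
              selected_k = sel$n_clusters,
              silhouette = sel$silhouette,
              assignments = ens$assignments,
              codec = aug$codec, bridge = bridge,
              ensembles = ens$ensembles,
              feature_names = colnames(xm))
  class(out) <- "hybrid_core"
  out
}

#' Predict from a fitted hybrid core
#'
#' The bridge SVM predicts a composite code per sample; the code's cluster
#' component routes the sample to that cluster's ensemble, which
#' soft-votes the final class probabilities.
#'
#' @param object A `hybrid_core`.
#' @param newdata Feature matrix or `feature_table` in the same space the
#'   core was fitted on.
#' @param type `"class"`, `"prob"`, or `"full"` (class + routed cluster +
#'   probability matrix); default `"full"`.
#' @param ... Unused.
#' @return Per `type`; `"full"` returns a `hybrid_prediction` list.
#' @export
predict.hybrid_core <- function(object, newdata,
                                type = c("full", "class", "prob"), ...) {
  type <- match.arg(type)
  xm <- ft_values(newdata)
  if (ncol(xm) != length(object$feature_names)) {
    stop("feature dimension mismatch: got ", ncol(xm), ", expected ",
         length(object$feature_names))
  }
  codes <- as.character(predict(object$bridge, xm))
  clusters <- object$codec$cluster[match(codes, object$codec$code)]
  probs <- matrix(NA_real_, nrow(xm), length(object$classes),
                  dimnames = list(rownames(xm), object$classes))
  for (cl in unique(clusters)) {
    rows <- which(clusters == cl)
    ensemble <- object$ensembles[[as.character(cl)]]
    probs[rows, ] <- combine_votes(ensemble, xm[rows, , drop = FALSE],
                                   object$classes, object$config$voting)
  }
  cls <- argmax_class(probs)
  res <- list(class = cls, cluster = as.integer(clusters), prob = probs)
  class(res) <- "hybrid_prediction"
  switch(type, full = res, class = cls, prob = probs)
}

#' Fit the full hybrid pipeline from a labelled sequence dataset
#'
#' Composes Phase 1 (k-mer featurization, min-max normalization, LDA
#' projection — all fitted on the given training data only) with the
#' Phase 2-5 core. All randomness derives from `config$seed`.
#'
#' @param dataset A `labeled_dataset`.
#' @param k k-mer length; default 3.
#' @param mode `"frequency"` or `"counts"`.
#' @param canonical Collapse reverse-complement k-mers; default `FALSE`.
#' @param normalize Apply min-max scaling; default `TRUE`.
#' @param n_components LDA components (default classes - 1); `0` skips the
#'   projection.
#' @param config A [hybrid_config()].
#' @return A `hybrid_model` containing the fitted transforms and core.
#' @export
fit_hybrid <- function(dataset, k = 3, mode = "frequency",
                       canonical = FALSE, normalize = TRUE,
                       n_components = NULL, config = hybrid_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  ft <- featurize_dataset(dataset, k = k, mode = mode, canonical = canonical)
  minmax <- NULL
  if (normalize) {
    minmax <- fit_minmax(ft)
    ft <- apply_minmax(minmax, ft)
  }
  lda <- NULL
  if (is.null(n_components) || n_components > 0) {
    lda <- fit_lda(ft, n_components = n_components)
    ft <- apply_lda(lda, ft)
  }
  core <- fit_hybrid_core(ft, ft$labels, config)
  out <- list(k = k, mode = mode, canonical = canonical,
              minmax = minmax, lda = lda, core = core,
              classes = core$classes, config = config)
  class(out) <- "hybrid_model"
  out
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat("hybrid_model: k =", x$k, "| clusters =", x$core$n_clusters,
      "| combination =", paste(x$config$combination, collapse = "-"),
      "| classes =", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

# Apply the fitted Phase-1 transforms to new records/features.
transform_features <- function(model, newdata) {
  ft <- if (inherits(newdata, "labeled_dataset") ||
            inherits(newdata, "seq_records")) {
    featurize_dataset(newdata, k = model$k, mode = model$mode,
                      canonical = model$canonical)
  } else {
    newdata
  }
  if (!is.null(model$minmax)) ft <- apply_minmax(model$minmax, ft)
  if (!is.null(model$lda)) ft <- apply_lda(model$lda, ft)
  ft
}

#' Predict from a fitted hybrid pipeline
#'
#' @param object A `hybrid_model` from [fit_hybrid()].
#' @param newdata A `labeled_dataset`, `seq_records`, feature table or
#'   matrix. Sequences are featurized and transformed with the fitted
#'   Phase-1 states.
#' @param type `"full"` (default), `"class"`, or `"prob"`.
#' @param ... Unused.
#' @return As [predict.hybrid_core()].
#' @export
predict.hybrid_model <- function(object, newdata,
                                 type = c("full", "class", "prob"), ...) {
  type <- match.arg(type)
  ft <- transform_features(object, newdata)
  predict(object$core, ft, type = type)
}
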