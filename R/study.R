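#' Canonical configuration for the synthetic subgroup study
#'
#' The package's reference conditions for studying subgroup recovery and
#' hybrid-vs-plain behaviour on [generate_dataset()] output: the
#' four-learner RF-LR-KNN-MLP combination, and a Phase-2 logistic model
#' with substantial weight decay (5) so its probabilities stay off the
#' 0/1 rails — a saturated probability vector carries no within-class
#' geometry for Phase 3 to cluster. The accompanying pipeline choice
#' (documented in the methods vignette) is to skip the discriminant
#' projection (`fit_hybrid(..., n_components = 0)`): a Fisher projection
#' to classes - 1 dimensions minimises within-class scatter, which is
#' precisely the latent-subgroup signal the clustering phase consumes.
#'
#' @param seed Integer seed.
#' @param combination Base learners; default `c("RF", "LR", "KNN",
#'   "MLP")`, the best-performing combination in the benchmark.
#' @return A [hybrid_config()].
#' @export
study_config <- function(seed = 1,
                         combination = c("RF", "LR", "KNN", "MLP")) {
  hybrid_config(combination = combination,
                lr = list(decay = 5, maxit = 500),
                seed = seed)
}

#' Run one hold-out evaluation of the hybrid on a synthetic dataset
#'
#' Convenience wrapper used by the benchmark study: generates a dataset,
#' makes an unstratified 60/40 hold-out split, fits the hybrid (without
#' the discriminant projection, see [study_config()]) on the training
#' split and returns test accuracy plus subgroup-recovery diagnostics.
#'
#' @param spec A [synthetic_spec()].
#' @param config A [hybrid_config()]; default [study_config()] seeded
#'   from the spec.
#' @param train_fraction Hold-out training share; default 0.6.
#' @return List with `accuracy`, `selected_k`, `ari` (adjusted Rand index
#'   of training cluster assignments vs planted subgroups, `NA` when the
#'   mclust package is unavailable), `model`, `prediction`, `y_test`.
#' @export
run_study <- function(spec, config = study_config(seed = spec$seed),
                      train_fraction = 0.6) {
  gen <- generate_dataset(spec)
  ds <- gen$dataset
  split <- holdout_split(nrow(ds$records), train_fraction = train_fraction,
                         seed = stage_seed(spec$seed, 500))
  tr <- subset_dataset(ds, split$train)
  te <- subset_dataset(ds, split$test)
  model <- fit_hybrid(tr, n_components = 0, config = config)
  pred <- predict(model, te, type = "full")
  y_test <- as.character(te$labels[te$records$id])
  ari <- NA_real_
  if (requireNamespace("mclust", quietly = TRUE)) {
    ari <- mclust::adjustedRandIndex(model$core$assignments,
                                     gen$subgroups[tr$records$id])
  }
  list(accuracy = mean(pred$class == y_test),
       selected_k = model$core$selected_k,
       ari = ari, model = model, prediction = pred, y_test = y_test,
       train = tr, test = te, subgroups = gen$subgroups)
}
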