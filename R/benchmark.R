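#' Subset a labelled dataset by record index
#'
#' @param dataset A `labeled_dataset`.
#' @param idx Integer row indices into `dataset$records`.
#' @return A `labeled_dataset` restricted to those records. Class names
#'   are kept from the parent so train/test subsets share one class set.
#' @export
subset_dataset <- function(dataset, idx) {
  records <- dataset$records[idx, , drop = FALSE]
  class(records) <- class(dataset$records)
  out <- list(records = records,
              labels = dataset$labels[records$id],
              class_names = dataset$class_names)
  class(out) <- "labeled_dataset"
  out
}

#' Benchmark plain and hybrid ensembles over learner combinations
#'
#' For each requested combination, fits the plain soft-voting ensemble
#' and the hybrid variant on the same hold-out training split (Phase-1
#' transforms fitted on training rows only), evaluates both on the same
#' test split, and computes two-proportion Z and chi-squared tests of
#' each plain combination against the best hybrid of its arity. ROC and
#' precision-recall data are attached for the best hybrid overall
#' (binary tasks).
#'
#' @param dataset A `labeled_dataset`.
#' @param combinations Named list of learner-name vectors; default: all
#'   combinations of the requested `arities`.
#' @param arities Combination sizes to sweep when `combinations` is NULL;
#'   default `c(2, 3, 4, 5)` (10 + 10 + 5 + 1 = 26 rows, doubled by the
#'   hybrid variants).
#' @param k k-mer length; default 3.
#' @param n_components Discriminant components fitted on the training
#'   split (default classes - 1); `0` skips the projection, the setting
#'   used for latent-subgroup studies (see [study_config()]).
#' @param train_fraction Hold-out training share; default 0.6.
#' @param config A [hybrid_config()]; its `combination` field is replaced
#'   per benchmarked row.
#' @param positive Positive class for binary metrics; default first
#'   sorted class.
#' @param outdir Optional output directory; when given, metric tables
#'   (`metrics.csv`), test tables (`tests.csv`), confusion matrices
#'   (`confusion.json`), curve data (`roc.csv`, `pr.csv`), the resolved
#'   configuration (`config.json`), a log (`benchmark.log`) and schema
#'   metadata (`schema.json`) are written there.
#' @param seed Integer seed for the split (model seeds come from
#'   `config$seed`).
#' @param verbose Print per-combination progress; default `FALSE`.
#' @return A `benchmark_report` list: `metrics` (one row per plain and
#'   hybrid variant: Model, Precision, Recall, F_measure, Sensitivity,
#'   Accuracy), `tests` (pair, Z, chi2, p), `confusion`, `roc`, `pr`,
#'   `split`, `n_test`.
#' @export
run_benchmark <- function(dataset, combinations = NULL,
                          arities = c(2, 3, 4, 5), k = 3,
                          n_components = NULL, train_fraction = 0.6,
                          config = hybrid_config(), positive = NULL,
                          outdir = NULL, seed = 1, verbose = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (is.null(combinations)) {
    combinations <- do.call(c, lapply(arities, function(a)
      enumerate_combinations(LEARNER_NAMES, a)))
  }
  if (is.null(names(combinations))) {
    names(combinations) <- vapply(combinations, paste, character(1),
                                  collapse = "-")
  }
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    if (verbose) message(msg)
  }

  n <- nrow(dataset$records)
  split <- holdout_split(n, train_fraction = train_fraction, seed = seed)
  train_ds <- subset_dataset(dataset, split$train)
  test_ds <- subset_dataset(dataset, split$test)
  say("split: ", length(split$train), " train / ", length(split$test),
      " test")

  # Phase-1 transforms fitted on the training split only
  ft_train <- featurize_dataset(train_ds, k = k)
  minmax <- fit_minmax(ft_train)
  ft_train <- apply_minmax(minmax, ft_train)
  ft_test <- featurize_dataset(test_ds, k = k)
  ft_test <- apply_minmax(minmax, ft_test)
  if (is.null(n_components) || n_components > 0) {
    lda <- fit_lda(ft_train, n_components = n_components)
    ft_train <- apply_lda(lda, ft_train)
    ft_test <- apply_lda(lda, ft_test)
  }

  y_train <- ft_train$labels
  y_test <- as.character(ft_test$labels)
  if (is.null(positive)) positive <- sort(unique(y_test))[1]
  n_test <- length(y_test)

  rows <- list()
  correct <- list()
  hybrid_preds <- list()
  for (nm in names(combinations)) {
    combo <- combinations[[nm]]
    arity <- length(combo)
    say("combination ", nm)

    plain <- fit_softvote(ft_train, y_train, combo,
                          learner_params = config$learner_params,
                          voting = config$voting, seed = config$seed)
    plain_cls <- predict(plain, ft_test, type = "class")
    rows[[nm]] <- metric_row(nm, arity, "plain", y_test, plain_cls, positive)
    correct[[nm]] <- sum(plain_cls == y_test)

    hyb_name <- paste0("Hybrid-", nm)
    cfg <- config
    cfg$combination <- combo
    hyb <- fit_hybrid_core(ft_train, y_train, cfg)
    hyb_pred <- predict(hyb, ft_test, type = "full")
    say("  hybrid clusters: ", hyb$n_clusters)
    rows[[hyb_name]] <- metric_row(hyb_name, arity, "hybrid", y_test,
                                   hyb_pred$class, positive)
    correct[[hyb_name]] <- sum(hyb_pred$class == y_test)
    hybrid_preds[[hyb_name]] <- hyb_pred
  }
  metrics_df <- do.call(rbind, rows)
  rownames(metrics_df) <- NULL

  # significance of each plain combination vs the best hybrid of its arity
  tests <- list()
  for (a in sort(unique(metrics_df$arity))) {
    sub <- metrics_df[metrics_df$arity == a, , drop = FALSE]
    hyb_rows <- sub[sub$variant == "hybrid", , drop = FALSE]
    if (!nrow(hyb_rows)) next
    best_hyb <- hyb_rows$Model[which.max(hyb_rows$Accuracy)]
    for (m in sub$Model[sub$variant == "plain"]) {
      acc_a <- sub$Accuracy[sub$Model == m]
      acc_b <- hyb_rows$Accuracy[hyb_rows$Model == best_hyb]
      zt <- z_test(acc_a, acc_b, n_test)
      ct <- chi2_test(correct[[m]], correct[[best_hyb]], n_test)
      tests[[paste(m, best_hyb)]] <-
        data.frame(model = m, hybrid = best_hyb,
                   Z = zt$z_statistic, chi2 = ct$chi2_statistic,
                   p_value = zt$p_value, stringsAsFactors = FALSE)
    }
  }
  tests_df <- if (length(tests)) do.call(rbind, tests) else
    data.frame(model = character(0), hybrid = character(0),
               Z = numeric(0), chi2 = numeric(0), p_value = numeric(0))
  rownames(tests_df) <- NULL

  # confusion + curves for the best hybrid overall
  hyb_metrics <- metrics_df[metrics_df$variant == "hybrid", , drop = FALSE]
  best_name <- hyb_metrics$Model[which.max(hyb_metrics$Accuracy)]
  best_pred <- hybrid_preds[[best_name]]
  cm <- confusion(y_test, best_pred$class, positive = positive)
  roc <- pr <- NULL
  if (length(unique(y_test)) == 2) {
    scores <- best_pred$prob[, positive]
    roc <- roc_curve(y_test, scores, positive = positive)
    pr <- pr_curve(y_test, scores, positive = positive)
  }
  say("best hybrid: ", best_name)

  report <- list(metrics = metrics_df, tests = tests_df,
                 best_hybrid = best_name, confusion = cm,
                 roc = roc, pr = pr, split = split, n_test = n_test,
                 positive = positive, k = k, seed = seed)
  class(report) <- "benchmark_report"
  if (!is.null(outdir)) {
    write_benchmark(report, outdir, config, log_lines)
  }
  report
}

metric_row <- function(name, arity, variant, y_true, y_pred, positive) {
  cm <- confusion(y_true, y_pred, positive = positive)
  m <- suppressWarnings(metrics(cm))
  data.frame(Model = name, Precision = m$precision, Recall = m$recall,
             F_measure = m$f1, Sensitivity = m$sensitivity,
             Accuracy = m$accuracy, arity = arity, variant = variant,
             stringsAsFactors = FALSE)
}

write_benchmark <- function(report, outdir, config, log_lines) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$metrics, file.path(outdir, "metrics.csv"),
            row.names = FALSE)
  write.csv(report$tests, file.path(outdir, "tests.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(positive = report$confusion$positive,
         TP = report$confusion$TP, FP = report$confusion$FP,
         TN = report$confusion$TN, FN = report$confusion$FN,
         model = report$best_hybrid),
    file.path(outdir, "confusion.json"), auto_unbox = TRUE)
  if (!is.null(report$roc)) {
    write.csv(data.frame(threshold = report$roc$thresholds,
                         fpr = report$roc$fpr, tpr = report$roc$tpr),
              file.path(outdir, "roc.csv"), row.names = FALSE)
    write.csv(data.frame(threshold = report$pr$thresholds,
                         recall = report$pr$recall,
                         precision = report$pr$precision),
              file.path(outdir, "pr.csv"), row.names = FALSE)
  }
  cfg <- unclass(config)
  cfg$k <- report$k
  cfg$split_seed <- report$seed
  jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  writeLines(log_lines, file.path(outdir, "benchmark.log"))
  jsonlite::write_json(
    list(tool = "hybridseq",
         version = as.character(utils::packageVersion("hybridseq")),
         schema = 1L),
    file.path(outdir, "schema.json"), auto_unbox = TRUE)
  invisible(outdir)
}
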