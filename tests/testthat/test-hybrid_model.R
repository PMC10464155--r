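test_that("class probabilities are proper distributions in both modes", {
  set.seed(21)
  x <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- factor(rep(c("a", "b", "c"), each = 20))
  for (src in c("in_sample", "out_of_fold")) {
    P <- compute_class_probabilities(x, y, source = src, seed = 4)
    expect_equal(dim(P), c(60, 3))
    expect_equal(colnames(P), c("a", "b", "c"))
    expect_rows_sum_to_one(P)
  }
  expect_error(compute_class_probabilities(x, rep("a", 60)), "2 classes")
})

test_that("a separable 1-D problem drives probabilities past 0.99", {
  set.seed(22)
  x <- matrix(c(rnorm(20, -2, 0.3), rnorm(20, 2, 0.3)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c("neg", "pos"), each = 20)
  P <- compute_class_probabilities(x, y, seed = 1)
  expect_true(all(apply(P, 1, max) > 0.99))
})

test_that("silhouette selection recovers planted blobs and handles edge cases", {
  set.seed(23)
  # two well-separated blobs in probability space
  P <- rbind(cbind(runif(30, 0.9, 0.99), runif(30, 0.01, 0.1)),
             cbind(runif(30, 0.01, 0.1), runif(30, 0.9, 0.99)))
  P <- P / rowSums(P)
  sel <- select_cluster_count(P, c(2, 6), seed = 0)
  expect_equal(sel$n_clusters, 2L)
  expect_equal(length(sel$assignments), 60)

  # degenerate range [1,1] skips selection entirely
  sel1 <- select_cluster_count(P, c(1, 1), seed = 0)
  expect_equal(sel1$n_clusters, 1L)
  expect_true(all(sel1$assignments == 1L))

  # upper bound >= n is truncated with a warning
  expect_warning(sel2 <- select_cluster_count(P[1:5, ], c(2, 10), seed = 0),
                 "truncated")
  expect_lte(sel2$n_clusters, 4)

  expect_error(select_cluster_count(P[1, , drop = FALSE], c(2, 3)),
               "at least 2 samples")
})

test_that("label augmentation builds an invertible composite codec", {
  aug <- augment_labels(c(0, 0, 1, 1), c(0, 1, 0, 0))
  expect_equal(nlevels(aug$codes), 3)  # pairs {(0,0),(0,1),(1,0)}
  expect_equal(nrow(aug$codec), 3)
  # invertibility: every code decodes to exactly one (class, cluster) pair
  decoded <- aug$codec[match(as.character(aug$codes), aug$codec$code), ]
  expect_equal(decoded$class, as.character(c(0, 0, 1, 1)))
  expect_equal(decoded$cluster, c(0, 1, 0, 0))

  # single cluster: composite labels bijective with original labels
  aug1 <- augment_labels(c("a", "b", "a"), c(1, 1, 1))
  expect_equal(nlevels(aug1$codes), 2)

  # pair bound
  y <- sample(2, 50, replace = TRUE)
  cl <- sample(3, 50, replace = TRUE)
  expect_lte(nlevels(augment_labels(y, cl)$codes), 2 * 3)

  expect_error(augment_labels(1:3, 1:2), "equal length")
})

test_that("the bridge learns composite codes and degrades to a constant", {
  set.seed(24)
  x <- matrix(c(rnorm(20, -2), rnorm(20, 0), rnorm(20, 2)), ncol = 1,
              dimnames = list(NULL, "f"))
  codes <- factor(rep(c("a@1", "a@2", "b@1"), each = 20))
  br <- fit_bridge(x, codes, seed = 1)
  acc <- mean(as.character(predict(br, x)) == as.character(codes))
  expect_gte(acc, max(table(codes)) / length(codes))  # beats majority rate
  # refit with the same seed gives identical predictions
  br2 <- fit_bridge(x, codes, seed = 1)
  expect_identical(predict(br2, x), predict(br, x))

  const <- fit_bridge(x, factor(rep("only@1", 60)), seed = 1)
  expect_true(all(predict(const, x) == "only@1"))
})

test_that("per-cluster ensembles fit every learner, merge small clusters, and
           degrade single-class clusters to constants", {
  set.seed(25)
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- factor(rep(c("a", "b"), each = 20))
  assign2 <- rep(c(1, 2), 20)
  ens <- fit_cluster_ensembles(x, y, assign2, c("KNN", "MLP"),
                               min_cluster_size = 5, seed = 1)
  expect_length(ens$ensembles, 2)
  expect_length(unlist(ens$ensembles, recursive = FALSE), 4)

  # single-class cluster -> constant predictor with probability one
  pure <- c(rep(1, 20), rep(2, 20))  # cluster 1 = class a only
  ens2 <- fit_cluster_ensembles(x, y, pure, "KNN", seed = 1)
  l <- ens2$ensembles[["1"]]$KNN
  expect_s3_class(l, "constant_learner")
  p <- predict_learner(l, x[1:3, ])
  expect_equal(unname(p[, "a"]), c(1, 1, 1))

  # a cluster below min_cluster_size is merged into its nearest neighbour
  tiny <- c(rep(1, 37), rep(2, 3))
  ens3 <- fit_cluster_ensembles(x, y, tiny, "KNN", min_cluster_size = 5,
                                seed = 1)
  expect_length(ens3$ensembles, 1)
  expect_true(all(ens3$assignments == 1))

  expect_error(fit_cluster_ensembles(x, y, assign2, character(0)),
               "non-empty")
})

test_that("hybrid prediction routes through the bridge with proper probabilities", {
  ds <- separable_dataset(seed = 31)
  model <- fit_hybrid(ds, config = hybrid_config(cluster_range = c(2, 4),
                                                 combination = c("LR", "KNN"),
                                                 seed = 2))
  pred <- predict(model, ds, type = "full")
  expect_rows_sum_to_one(pred$prob)
  expect_true(all(pred$class %in% model$classes))
  expect_true(all(pred$cluster %in% model$core$codec$cluster))
  expect_equal(pred$class, colnames(pred$prob)[apply(pred$prob, 1, which.max)])
})

test_that("the degenerate single-cluster hybrid equals the plain soft-vote ensemble", {
  combos <- list(c("SVM", "KNN"), c("RF", "LR"), c("LR", "MLP"))
  for (s in 1:5) {
    ds <- separable_dataset(seed = 40 + s)
    combo <- combos[[1 + (s %% length(combos))]]
    cfg <- hybrid_config(cluster_range = c(1, 1), combination = combo,
                         seed = s)
    model <- fit_hybrid(ds, config = cfg)
    ft <- predict(model, ds, type = "class")
    feats <- featurize_dataset(ds)
    feats <- apply_minmax(model$minmax, feats)
    feats <- apply_lda(model$lda, feats)
    plain <- fit_softvote(feats, feats$labels, combo, seed = s)
    expect_identical(unname(ft), unname(predict(plain, feats)))
  }
})

test_that("hybrid fits are reproducible from the config seed", {
  spec <- synthetic_spec(samples_per_subgroup = 15, sequence_length = 400,
                         seed = 3)
  ds <- generate_dataset(spec)$dataset
  cfg <- study_config(seed = 9)
  m1 <- fit_hybrid(ds, n_components = 0, config = cfg)
  m2 <- fit_hybrid(ds, n_components = 0, config = cfg)
  expect_identical(m1$core$assignments, m2$core$assignments)
  expect_identical(m1$core$codec, m2$core$codec)
  expect_identical(predict(m1, ds, type = "class"),
                   predict(m2, ds, type = "class"))
})

test_that("routing beats the plain ensemble when subgroups oppose the class signal", {
  # a linear ensemble cannot separate interleaved subgroups; the hybrid can
  accs <- vapply(1:6, function(s) {
    spec <- synthetic_spec(seed = s)
    st <- run_study(spec, config = study_config(seed = s, combination = "LR"))
    ftr <- featurize_dataset(st$train)
    mm <- fit_minmax(ftr)
    plain <- fit_softvote(apply_minmax(mm, ftr),
                          ftr$labels, "LR", seed = s)
    fte <- apply_minmax(mm, featurize_dataset(st$test))
    c(hybrid = st$accuracy,
      plain = mean(predict(plain, fte) == st$y_test))
  }, numeric(2))
  # one-sided paired comparison: hybrid never worse, strictly better on average
  expect_true(all(accs["hybrid", ] >= accs["plain", ]))
  expect_gt(mean(accs["hybrid", ]), mean(accs["plain", ]))
})

test_that("combination enumeration matches the benchmark row families", {
  expect_length(enumerate_combinations(arity = 2), 10)
  expect_length(enumerate_combinations(arity = 3), 10)
  expect_length(enumerate_combinations(arity = 4), 5)
  combos5 <- enumerate_combinations(arity = 5)
  expect_length(combos5, 1)
  expect_equal(names(combos5), "SVM-RF-LR-KNN-MLP")
  expect_error(enumerate_combinations(arity = 6), "arity")
  expect_error(enumerate_combinations(arity = 0), "arity")
})
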