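test_that("min-max scaling maps training data to [0,1] and extrapolates beyond", {
  x <- matrix(c(1, 2, 3, 10, 20, 30), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  st <- fit_minmax(x)
  expect_equal(unname(st$min), c(1, 10))
  expect_equal(unname(st$max), c(3, 30))
  scaled <- apply_minmax(st, x)
  expect_equal(unname(scaled[, 1]), c(0, 0.5, 1))
  expect_true(all(scaled >= 0 & scaled <= 1))

  # unseen value outside the training range maps outside [0,1], unclipped
  test <- matrix(c(4, 15), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(unname(apply_minmax(st, test)[1, 1]), 1.5)

  # constant feature maps to 0 rather than dividing by zero
  const <- matrix(c(5, 5, 1, 2), ncol = 2,
                  dimnames = list(NULL, c("c", "v")))
  stc <- fit_minmax(const)
  expect_true(all(apply_minmax(stc, const)[, "c"] == 0))

  # idempotent on already-normalized data fitted to itself
  st2 <- fit_minmax(scaled)
  expect_equal(apply_minmax(st2, scaled), scaled)

  expect_error(fit_minmax(matrix(numeric(0), 0, 2)), "empty")
  bad <- matrix(1:3, ncol = 1, dimnames = list(NULL, "other"))
  expect_error(apply_minmax(st, bad), "feature names")
})

test_that("LDA direction matches the closed-form Fisher solution", {
  set.seed(42)
  n <- 30
  x <- rbind(cbind(rnorm(n, 0, 1), rnorm(n, 0, 0.5)),
             cbind(rnorm(n, 3, 1), rnorm(n, 1.5, 0.5)))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("a", "b"), each = n)

  proj <- fit_lda(x, y, n_components = 1)

  # hand oracle: w ~ Sw^-1 (mu1 - mu2)
  mu1 <- colMeans(x[y == "a", ]); mu2 <- colMeans(x[y == "b", ])
  Sw <- crossprod(sweep(x[y == "a", ], 2, mu1)) +
    crossprod(sweep(x[y == "b", ], 2, mu2))
  w0 <- solve(Sw, mu1 - mu2)
  cosine <- sum(proj$rotation[, 1] * w0) /
    sqrt(sum(proj$rotation[, 1]^2) * sum(w0^2))
  expect_equal(abs(cosine), 1, tolerance = 1e-8)

  # sign convention: first nonzero coefficient positive
  expect_gt(proj$rotation[which(abs(proj$rotation[, 1]) > 1e-12)[1], 1], 0)

  # MASS::lda as independent cross-check of the discriminant direction
  ml <- MASS::lda(x, grouping = y)
  cos2 <- sum(proj$rotation[, 1] * ml$scaling[, 1]) /
    sqrt(sum(proj$rotation[, 1]^2) * sum(ml$scaling[, 1]^2))
  expect_equal(abs(cos2), 1, tolerance = 1e-6)
})

test_that("LDA separates well-separated Gaussian clouds by > 3 pooled sds", {
  set.seed(7)
  n <- 50
  x <- rbind(matrix(rnorm(n * 4, 0, 1), n, 4),
             matrix(rnorm(n * 4, 4, 1), n, 4))
  colnames(x) <- paste0("f", 1:4)
  y <- rep(c("a", "b"), each = n)
  proj <- fit_lda(x, y)
  z <- apply_lda(proj, x)[, 1]
  pooled_sd <- sqrt((var(z[y == "a"]) + var(z[y == "b"])) / 2)
  expect_gt(abs(mean(z[y == "a"]) - mean(z[y == "b"])) / pooled_sd, 3)
})

test_that("LDA enforces the rank bound and rejects degenerate inputs", {
  set.seed(8)
  for (C in 2:4) {
    n <- 20
    x <- do.call(rbind, lapply(seq_len(C), function(cl)
      matrix(rnorm(n * 5, mean = 2 * cl), n, 5)))
    colnames(x) <- paste0("f", 1:5)
    y <- rep(letters[seq_len(C)], each = n)
    expect_error(fit_lda(x, y, n_components = C), "exceeds classes - 1")
    proj <- fit_lda(x, y)
    expect_equal(proj$n_components, C - 1L)
    expect_equal(ncol(apply_lda(proj, x)), C - 1L)
  }
  x1 <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_lda(x1, rep("only", 10)), "at least 2 classes")
})

test_that("projection is reproducible and invariant to feature rescaling", {
  set.seed(9)
  n <- 40
  x <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)), cbind(rnorm(n, 2), rnorm(n, 1)))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("a", "b"), each = n)
  proj <- fit_lda(x, y)
  expect_identical(apply_lda(proj, x), apply_lda(proj, x))

  standardized_sep <- function(xx) {
    p <- fit_lda(xx, y)
    z <- apply_lda(p, xx)[, 1]
    abs(mean(z[y == "a"]) - mean(z[y == "b"])) /
      sqrt((var(z[y == "a"]) + var(z[y == "b"])) / 2)
  }
  x10 <- x
  x10[, 1] <- x10[, 1] * 10
  expect_equal(standardized_sep(x), standardized_sep(x10), tolerance = 1e-6)
})

test_that("LDA tolerates collinear k-mer tables via the ridge fallback", {
  files <- write_tiny_fasta()
  ds <- read_labels(files$labels, read_fasta(files$fasta))
  spec <- synthetic_spec(samples_per_subgroup = 10, sequence_length = 200,
                         seed = 3)
  ft <- featurize_dataset(generate_dataset(spec)$dataset)
  # frequency rows sum to 1, so columns are exactly collinear
  proj <- fit_lda(ft)
  expect_true(all(is.finite(proj$rotation)))
})

test_that("fitted preprocessing states serialize to JSON and back", {
  set.seed(10)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c("u", "v"), each = 10)
  st <- fit_minmax(x)
  proj <- fit_lda(apply_minmax(st, x), y)

  f1 <- withr::local_tempfile(fileext = ".json")
  write_preprocess_state(st, f1)
  st2 <- read_preprocess_state(f1)
  expect_equal(st2$min, st$min)
  expect_equal(st2$max, st$max)
  expect_equal(apply_minmax(st2, x), apply_minmax(st, x))

  f2 <- withr::local_tempfile(fileext = ".json")
  write_preprocess_state(proj, f2)
  proj2 <- read_preprocess_state(f2)
  expect_equal(unname(proj2$rotation), unname(proj$rotation))
  expect_equal(apply_lda(proj2, apply_minmax(st, x)),
               apply_lda(proj, apply_minmax(st, x)))
})
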