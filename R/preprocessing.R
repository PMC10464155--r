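#' Fit min-max normalization statistics
#'
#' Records per-feature minima and maxima from the training rows only, for
#' linear rescaling onto [0, 1]. Test-time values outside the training range
#' deliberately map outside [0, 1] (no clipping), since unseen samples may
#' exceed the training range.
#'
#' @param table A `feature_table` or numeric matrix with >= 1 row.
#' @return A `minmax_state` with `min`, `max` and `feature_names`.
#' @export
fit_minmax <- function(table) {
  x <- ft_values(table)
  if (nrow(x) < 1) stop("cannot fit min-max on an empty table")
  out <- list(min = apply(x, 2, min),
              max = apply(x, 2, max),
              feature_names = colnames(x))
  class(out) <- "minmax_state"
  out
}

#' Apply min-max normalization
#'
#' Maps each value to (x - x_min) / (x_max - x_min) with the fitted
#' training statistics. A feature that was constant in training (min = max)
#' maps to 0 everywhere, avoiding a zero denominator. Out-of-range test
#' values are not clipped.
#'
#' @param state A fitted `minmax_state`.
#' @param table A `feature_table` or matrix over the same features.
#' @return The rescaled table, same type as the input.
#' @export
apply_minmax <- function(state, table) {
  stopifnot(inherits(state, "minmax_state"))
  x <- ft_values(table)
  if (!identical(colnames(x), state$feature_names)) {
    stop("feature names do not match the fitted min-max state")
  }
  rng <- state$max - state$min
  scaled <- sweep(x, 2, state$min, "-")
  nz <- rng > 0
  scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2, rng[nz], "/")
  scaled[, !nz] <- 0
  ft_rewrap(table, scaled)
}

#' Fit a Fisher linear discriminant projection
#'
#' Finds the directions maximizing the Fisher criterion: between-class mean
#' separation over within-class scatter. At most `classes - 1` components
#' exist. When the within-class scatter matrix is (numerically) singular —
#' routine for collinear k-mer tables — a ridge term
#' `1e-6 * trace(Sw) / d` is added to its diagonal. Directions are
#' deterministic up to sign; the sign is fixed so each component's first
#' nonzero coefficient is positive.
#'
#' @param table A `feature_table` or matrix.
#' @param labels Class labels (factor/character); taken from the table when
#'   omitted.
#' @param n_components Number of discriminant directions; default
#'   `nlevels - 1`.
#' @return An `lda_projection` with `rotation` (features x components),
#'   `center` (grand mean), `class_means` and `n_components`.
#' @export
fit_lda <- function(table, labels = NULL, n_components = NULL) {
  x <- ft_values(table)
  if (is.null(labels) && inherits(table, "feature_table")) labels <- table$labels
  if (is.null(labels)) stop("labels are required to fit LDA")
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2) stop("LDA requires at least 2 classes")
  max_comp <- nlevels(y) - 1L
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp) {
    stop("n_components (", n_components, ") exceeds classes - 1 (",
         max_comp, ")")
  }
  d <- ncol(x)
  grand <- colMeans(x)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (cl in levels(y)) {
    rows <- x[y == cl, , drop = FALSE]
    mu <- colMeans(rows)
    centered <- sweep(rows, 2, mu)
    Sw <- Sw + crossprod(centered)
    dm <- mu - grand
    Sb <- Sb + nrow(rows) * tcrossprod(dm)
  }
  # ridge only when Sw is numerically singular
  if (d == 0) stop("no features")
  if (!all(is.finite(Sw)) || rcond_safe(Sw) < 1e-12) {
    Sw <- Sw + diag(1e-6 * sum(diag(Sw)) / d, d)
  }
  M <- solve(Sw, Sb)
  eig <- eigen(M)
  ord <- order(Re(eig$values), decreasing = TRUE)
  W <- Re(eig$vectors[, ord[seq_len(n_components)], drop = FALSE])
  # unit length, first nonzero coefficient positive
  for (j in seq_len(ncol(W))) {
    W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
    nzi <- which(abs(W[, j]) > 1e-12)[1]
    if (!is.na(nzi) && W[nzi, j] < 0) W[, j] <- -W[, j]
  }
  rownames(W) <- colnames(x)
  colnames(W) <- paste0("LD", seq_len(ncol(W)))
  class_means <- do.call(rbind, lapply(levels(y), function(cl) {
    colMeans(x[y == cl, , drop = FALSE])
  }))
  rownames(class_means) <- levels(y)
  out <- list(rotation = W, center = grand, class_means = class_means,
              n_components = as.integer(n_components),
              feature_names = colnames(x))
  class(out) <- "lda_projection"
  out
}

rcond_safe <- function(m) {
  tryCatch(rcond(m), error = function(e) 0)
}

#' Project features onto fitted discriminant directions
#'
#' @param projection A fitted `lda_projection`.
#' @param table A `feature_table` or matrix over the same features.
#' @return The projected table (columns `LD1`, ...), same type as input.
#' @export
apply_lda <- function(projection, table) {
  stopifnot(inherits(projection, "lda_projection"))
  x <- ft_values(table)
  if (ncol(x) != nrow(projection$rotation)) {
    stop("feature dimension mismatch: table has ", ncol(x),
         " features, projection expects ", nrow(projection$rotation))
  }
  proj <- sweep(x, 2, projection$center) %*% projection$rotation
  rownames(proj) <- rownames(x)
  ft_rewrap(table, proj)
}

#' Serialize a fitted preprocessing state to JSON
#'
#' Writes the min-max arrays or the LDA projection matrix so a train/test
#' separation is reproducible outside the fitting session.
#'
#' @param state A `minmax_state` or `lda_projection`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_preprocess_state <- function(state, path) {
  payload <- unclass(state)
  payload$.class <- class(state)[1]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a preprocessing state written by [write_preprocess_state()]
#'
#' @param path JSON path.
#' @return The restored `minmax_state` or `lda_projection`.
#' @export
read_preprocess_state <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- raw$.class
  raw$.class <- NULL
  if (cls == "minmax_state") {
    out <- list(min = setNames(as.numeric(raw$min), raw$feature_names),
                max = setNames(as.numeric(raw$max), raw$feature_names),
                feature_names = raw$feature_names)
  } else {
    W <- as.matrix(raw$rotation)
    rownames(W) <- raw$feature_names
    colnames(W) <- paste0("LD", seq_len(ncol(W)))
    cm <- as.matrix(raw$class_means)
    out <- list(rotation = W,
                center = setNames(as.numeric(raw$center), raw$feature_names),
                class_means = cm,
                n_components = as.integer(raw$n_components),
                feature_names = raw$feature_names)
  }
  class(out) <- cls
  out
}
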