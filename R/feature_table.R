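#' Feature table container
#'
#' A samples-by-features numeric matrix with sample ids as row names,
#' feature names as column names and an optional per-sample label factor.
#'
#' @param values Numeric matrix (samples x features) with dimnames.
#' @param labels Optional factor (or character) of per-sample class labels.
#' @param meta Optional list of provenance fields (k, mode, canonical, ...).
#' @return A `feature_table` object.
#' @export
feature_table <- function(values, labels = NULL, meta = list()) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- as.character(seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(values))
    if (!is.factor(labels)) labels <- factor(labels)
  }
  out <- list(values = values, labels = labels, meta = meta)
  class(out) <- "feature_table"
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$values), "samples x", ncol(x$values),
      "features")
  if (!is.null(x$labels)) {
    cat(";", nlevels(x$labels), "classes (",
        paste(levels(x$labels), collapse = ", "), ")")
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# Accept a feature_table or a bare matrix wherever features are consumed.
ft_values <- function(x) {
  if (inherits(x, "feature_table")) x$values else as.matrix(x)
}

ft_rewrap <- function(template, values) {
  if (inherits(template, "feature_table")) {
    feature_table(values, labels = template$labels, meta = template$meta)
  } else {
    values
  }
}

#' Write a feature table to delimited text
#'
#' First column `id`, one column per feature, optional final `label`
#' column. A JSON sidecar (`<path>.vocab.json`) records the feature names
#' and any k-mer metadata so the table can be reloaded unambiguously.
#'
#' @param table A `feature_table`.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @param sidecar Write the JSON sidecar; default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, sidecar = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$labels)) df$label <- as.character(table$labels)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(feature_names = colnames(table$values), meta = table$meta),
      paste0(path, ".vocab.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to the delimited table.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("id" %in% names(df))
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    df$label <- NULL
  }
  ids <- df$id
  df$id <- NULL
  values <- as.matrix(df)
  rownames(values) <- ids
  meta <- list()
  sidecar <- paste0(path, ".vocab.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)$meta
    if (is.null(meta)) meta <- list()
  }
  feature_table(values, labels = labels, meta = as.list(meta))
}
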