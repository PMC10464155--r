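#' Read sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a `seq_records` data frame.
#' The record id is the header token before the first whitespace; the full
#' header line (without the leading `>`) is kept as the description.
#' Sequences are uppercased on read so that k-mer identity is
#' case-insensitive.
#'
#' @param path Path to a FASTA file.
#' @param strict Logical; if `TRUE`, records with an empty sequence body are
#'   an error. Default `FALSE`.
#' @return A data frame of class `seq_records` with columns `id`,
#'   `description` and `sequence`, one row per FASTA record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 first gene", "acgt", "ACGT", ">g2", "TTTT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- names(set)
  if (is.null(headers)) headers <- character(0)
  ids <- sub("\\s.*$", "", headers)
  seqs <- toupper(as.character(set))
  if (length(ids) && any(!nzchar(ids))) {
    stop("FASTA record with empty header in '", path, "'")
  }
  if (strict && length(seqs) && any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)]
    stop("empty sequence body for record(s): ", paste(bad, collapse = ", "))
  }
  seq_records(ids, headers, seqs)
}

#' Construct a seq_records table
#'
#' @param id Character vector of record ids.
#' @param description Character vector of full header lines.
#' @param sequence Character vector of (uppercase) sequences.
#' @return A `seq_records` data frame.
#' @export
seq_records <- function(id = character(0), description = id,
                        sequence = character(0)) {
  stopifnot(length(id) == length(sequence))
  df <- data.frame(id = as.character(id),
                   description = as.character(description),
                   sequence = toupper(as.character(sequence)),
                   stringsAsFactors = FALSE)
  class(df) <- c("seq_records", "data.frame")
  df
}

#' Write sequences to a FASTA file
#'
#' Emits 60-column wrapped FASTA using the stored description as the header,
#' so that `read_fasta(write_fasta(x))` round-trips normalized records.
#'
#' @param records A `seq_records` data frame.
#' @param path Output file path.
#' @param width Line-wrap width, default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(inherits(records, "data.frame"))
  set <- Biostrings::BStringSet(records$sequence)
  hdr <- records$description
  hdr[!nzchar(hdr)] <- records$id[!nzchar(hdr)]
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Join a label table onto sequence records
#'
#' Reads a delimited text file with header columns `id` and `label`
#' (TSV or CSV, auto-detected from the delimiter on the header line) and
#' joins it to a set of records, producing a `labeled_dataset`.
#'
#' @param path Path to the label table.
#' @param records A `seq_records` data frame (from [read_fasta()]).
#' @param strict Logical; if `TRUE` (default) a record without a label is an
#'   error. Label rows whose id matches no record are an error in strict
#'   mode, a warning (and skip) otherwise. Duplicate ids are always an error.
#' @return A `labeled_dataset`: list with `records`, `labels` (named
#'   character vector, record id -> class) and `class_names` (sorted unique).
#' @export
read_labels <- function(path, records, strict = TRUE) {
  if (!file.exists(path)) stop("label file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("id", "label") %in% names(tab))) {
    stop("label table must have header columns 'id' and 'label'")
  }
  tab$id <- as.character(tab$id)
  tab$label <- as.character(tab$label)
  if (anyDuplicated(tab$id)) {
    stop("duplicate id(s) in label table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  unknown <- setdiff(tab$id, records$id)
  if (length(unknown)) {
    msg <- paste0("label rows with unknown id(s): ",
                  paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg, "; skipped")
    tab <- tab[!tab$id %in% unknown, , drop = FALSE]
  }
  missing <- setdiff(records$id, tab$id)
  if (length(missing) && strict) {
    stop("record(s) without a label: ", paste(missing, collapse = ", "))
  }
  labels <- setNames(tab$label, tab$id)
  labeled_dataset(records, labels)
}

#' Construct a labeled dataset
#'
#' @param records A `seq_records` data frame.
#' @param labels Named character vector mapping record id to class label;
#'   an unnamed vector of `nrow(records)` labels is taken in record order.
#' @return A `labeled_dataset` object.
#' @export
labeled_dataset <- function(records, labels) {
  if (is.null(names(labels))) {
    stopifnot(length(labels) == nrow(records))
    labels <- setNames(as.character(labels), records$id)
  }
  labels <- labels[intersect(records$id, names(labels))]
  out <- list(records = records,
              labels = labels,
              class_names = sort(unique(unname(labels))))
  class(out) <- "labeled_dataset"
  out
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", nrow(x$records), "records,",
      length(x$labels), "labelled,",
      length(x$class_names), "classes (",
      paste(x$class_names, collapse = ", "), ")\n")
  invisible(x)
}

#' Validate a nucleotide sequence
#'
#' Counts symbols outside the A/C/G/T alphabet. In strict mode such symbols
#' are an error naming the offending positions; in lenient mode the record
#' is kept unchanged (downstream k-mer windows containing them are skipped).
#'
#' @param record A single-row `seq_records` data frame, or a character
#'   sequence.
#' @param strict Logical, default `FALSE`.
#' @return A list with `record` (unchanged) and `report` (list with
#'   `ambiguous` count and `positions` of non-ACGT symbols).
#' @export
validate_sequence <- function(record, strict = FALSE) {
  seq <- if (is.character(record)) toupper(record[1]) else record$sequence[1]
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (strict && length(bad)) {
    id <- if (is.character(record)) "<sequence>" else record$id[1]
    stop("sequence '", id, "' has ", length(bad),
         " non-ACGT symbol(s) at position(s): ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ..." else "")
  }
  list(record = record,
       report = list(ambiguous = length(bad), positions = bad))
}
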