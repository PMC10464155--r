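#' k-mer vocabulary
#'
#' Enumerates all 4^k k-mers over the A/C/G/T alphabet in lexicographic
#' order, optionally collapsed into reverse-complement (canonical)
#' equivalence classes — each k-mer is represented by the lexicographically
#' smaller of itself and its reverse complement (32 classes for k = 3).
#'
#' @param k Substring length, integer >= 1.
#' @param canonical Logical; collapse reverse complements. Default `FALSE`.
#' @return A `kmer_vocabulary`: list with `k`, `alphabet`, `canonical`,
#'   `feature_names` and `canonical_map` (full k-mer -> feature name).
#' @export
kmer_vocabulary <- function(k = 3, canonical = FALSE) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("k must be a single integer >= 1")
  }
  k <- as.integer(k)
  alphabet <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), k), stringsAsFactors = FALSE))
  all_kmers <- sort(do.call(paste0, grid))
  canon <- pmin(all_kmers, revcomp(all_kmers))
  feature_names <- if (canonical) sort(unique(canon)) else all_kmers
  out <- list(k = k, alphabet = alphabet, canonical = canonical,
              feature_names = feature_names,
              canonical_map = setNames(canon, all_kmers))
  class(out) <- "kmer_vocabulary"
  out
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Enumerate the k-mers of a sequence
#'
#' Slides a window of length `k` with stride 1 over the sequence and returns
#' the windows, in position order. Windows containing symbols outside
#' A/C/G/T (e.g. `N`) are skipped.
#'
#' @param sequence A single nucleotide string.
#' @param k Substring length, integer >= 1.
#' @return Character vector of k-mers; empty when the sequence is shorter
#'   than `k`.
#' @examples
#' enumerate_kmers("ATCGATCGATCG", 3)
#' @export
enumerate_kmers <- function(sequence, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("k must be a single integer >= 1")
  }
  sequence <- toupper(sequence[1])
  n <- nchar(sequence)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1)
  kmers <- substring(sequence, starts, starts + k - 1)
  kmers[!grepl("[^ACGT]", kmers)]
}

#' k-mer count or frequency vector for one sequence
#'
#' Tallies the sequence's valid k-mer windows over the vocabulary. In
#' frequency mode counts are divided by the number of valid windows, so the
#' row sums to 1; a sequence with zero valid windows yields an all-zero row
#' with a warning (never NaN).
#'
#' @param sequence A single nucleotide string.
#' @param vocab A [kmer_vocabulary()].
#' @param mode `"counts"` or `"frequency"` (default).
#' @return Named numeric vector over `vocab$feature_names`.
#' @export
kmer_vector <- function(sequence, vocab, mode = c("frequency", "counts")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vocab, "kmer_vocabulary"))
  kmers <- enumerate_kmers(sequence, vocab$k)
  if (vocab$canonical) kmers <- unname(vocab$canonical_map[kmers])
  counts <- table(factor(kmers, levels = vocab$feature_names))
  v <- setNames(as.numeric(counts), vocab$feature_names)
  if (mode == "frequency") {
    total <- sum(v)
    if (total == 0) {
      warning("sequence yielded zero valid k-mer windows; returning zero row")
    } else {
      v <- v / total
    }
  }
  v
}

#' Collapse a plain k-mer vector onto canonical reverse-complement classes
#'
#' Adds each k-mer's mass to the lexicographically smaller of the pair
#' (k-mer, reverse complement). Total mass is conserved; palindromic k-mers
#' map to themselves.
#'
#' @param vector Named numeric vector over the full 4^k vocabulary.
#' @param vocab The (non-canonical) [kmer_vocabulary()] the vector was
#'   built with.
#' @return Named numeric vector over the canonical class representatives.
#' @export
collapse_reverse_complement <- function(vector, vocab) {
  stopifnot(inherits(vocab, "kmer_vocabulary"), !vocab$canonical)
  stopifnot(identical(names(vector), vocab$feature_names))
  canon <- vocab$canonical_map[names(vector)]
  out <- tapply(vector, canon, sum)
  out <- out[sort(names(out))]
  setNames(as.numeric(out), names(out))
}

#' Featurize a labelled dataset as a k-mer table
#'
#' One row per record, columns in fixed lexicographic k-mer order, labels
#' carried through. Deterministic: the same input always yields the same
#' table.
#'
#' @param dataset A `labeled_dataset` (or bare `seq_records`).
#' @param k Substring length; default 3, the value at which the feature
#'   sweep over k in \{1, 2, 3, 5, 6\} performs best for gene-scale input.
#' @param mode `"frequency"` (default) or `"counts"`.
#' @param canonical Collapse reverse complements; default `FALSE`.
#' @return A [feature_table()] with one row per record.
#' @export
featurize_dataset <- function(dataset, k = 3,
                              mode = c("frequency", "counts"),
                              canonical = FALSE) {
  mode <- match.arg(mode)
  records <- if (inherits(dataset, "labeled_dataset")) dataset$records else dataset
  vocab <- kmer_vocabulary(k, canonical)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    tryCatch(kmer_vector(records$sequence[i], vocab, mode),
             error = function(e) stop("record '", records$id[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  values <- do.call(rbind, rows)
  if (is.null(values)) {
    values <- matrix(0, 0, length(vocab$feature_names))
  }
  dimnames(values) <- list(records$id, vocab$feature_names)
  labels <- NULL
  if (inherits(dataset, "labeled_dataset")) {
    labels <- factor(unname(dataset$labels[records$id]),
                     levels = dataset$class_names)
  }
  feature_table(values, labels = labels,
                meta = list(k = vocab$k, mode = mode, canonical = canonical))
}
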