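# Shared fixtures and independent oracles, all built in code.

BASES <- c("A", "C", "G", "T")

random_sequence <- function(len, alphabet = BASES, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (len == 0) return("")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force k-mer tally: slice every substring, drop non-ACGT windows.
naive_kmer_counts <- function(seq, k, feature_names) {
  out <- setNames(numeric(length(feature_names)), feature_names)
  n <- nchar(seq)
  if (n >= k) {
    for (i in seq_len(n - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (w %in% feature_names) out[w] <- out[w] + 1
    }
  }
  out
}

# Mann-Whitney pairwise concordance (ties count 1/2) — AUC oracle.
auc_concordance <- function(y_true, scores, positive) {
  pos <- scores[y_true == positive]
  neg <- scores[y_true != positive]
  grid <- expand.grid(p = pos, n = neg)
  mean((grid$p > grid$n) + 0.5 * (grid$p == grid$n))
}

# Small labelled FASTA dataset written to a temp dir.
write_tiny_fasta <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fasta <- file.path(dir, "tiny.fasta")
  labels <- file.path(dir, "tiny.tsv")
  writeLines(c(
    ">g1 first gene", "acgtACGTacgt", "ACGT",
    ">g2 second", "TTTTCCCC",
    ">g3", "GGGGAAAA"), fasta)
  writeLines(c("id\tlabel", "g1\tHT", "g2\tCD", "g3\tCD"), labels)
  list(fasta = fasta, labels = labels)
}

# Quick two-class dataset without subgroup structure (linearly separable).
separable_dataset <- function(seed, n_per_class = 12, len = 300) {
  spec <- synthetic_spec(subgroups_per_class = 1,
                         samples_per_subgroup = n_per_class,
                         sequence_length = len, seed = seed)
  generate_dataset(spec)$dataset
}

expect_rows_sum_to_one <- function(m, tol = 1e-9) {
  expect_true(all(abs(rowSums(m) - 1) < tol))
}
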