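#' Specification for a synthetic labelled sequence dataset
#'
#' Describes a dataset of i.i.d. (or order-1 Markov) nucleotide sequences
#' organised as classes that each contain latent subgroups — the data
#' regime the hybrid model targets: class labels are observed, subgroup
#' membership is hidden and must be rediscovered by probability
#' clustering. Subgroup base compositions are placed by
#' [make_separable()]: all composition positions interleave the classes
#' along one composition axis, so each class carries opposing
#' within-class signal (one subgroup lies on the other class's side of
#' the midpoint) and no single linear boundary separates the classes.
#'
#' @param n_classes Number of observed classes; default 2.
#' @param subgroups_per_class Latent subgroups per class; default 2.
#' @param samples_per_subgroup Sequences per subgroup; default 60 (2 x 2 x
#'   60 = 240 records, the scale of a curated disease gene set).
#' @param sequence_length Bases per sequence; default 2000 (gene-like
#'   scale, fast to simulate).
#' @param divergence Non-negative scalar controlling between-subgroup
#'   composition separation; 0 makes every subgroup identical
#'   (classifier accuracy collapses to chance). Default 0.3.
#' @param base_composition Baseline A/C/G/T probabilities; default uniform.
#' @param seed Integer seed.
#' @return A `synthetic_spec` (with `compositions` filled in by
#'   [make_separable()]).
#' @export
synthetic_spec <- function(n_classes = 2, subgroups_per_class = 2,
                           samples_per_subgroup = 60,
                           sequence_length = 2000, divergence = 0.3,
                           base_composition = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25),
                           seed = 1) {
  stopifnot(n_classes >= 1, subgroups_per_class >= 1,
            samples_per_subgroup >= 1, sequence_length >= 1,
            divergence >= 0)
  if (length(base_composition) != 4 || any(base_composition < 0) ||
      abs(sum(base_composition) - 1) > 1e-8) {
    stop("base_composition must be 4 non-negative probabilities summing to 1")
  }
  out <- list(n_classes = as.integer(n_classes),
              subgroups_per_class = as.integer(subgroups_per_class),
              samples_per_subgroup = as.integer(samples_per_subgroup),
              sequence_length = as.integer(sequence_length),
              divergence = divergence,
              base_composition = base_composition,
              seed = as.integer(seed))
  class(out) <- "synthetic_spec"
  make_separable(out, divergence)
}

#' Set subgroup compositions for a target divergence
#'
#' Places the `n_classes * subgroups_per_class` subgroups at evenly spaced
#' positions `pos` in [-1, 1] along the composition direction
#' (+1, -1, +1, -1)/4 (A and G up, C and T down), assigning consecutive
#' positions to alternating classes. Each subgroup's composition is
#' `base * (1 + divergence * pos * direction)`. Expected k-mer profiles
#' therefore separate monotonically in `divergence`, classes interleave
#' along the axis, and `divergence = 0` collapses all subgroups onto the
#' base composition. Probabilities pushed below 0.01 are clipped and the
#' composition renormalized, with a warning.
#'
#' @param spec A `synthetic_spec`.
#' @param divergence Non-negative scalar.
#' @return The spec with `divergence` and per-subgroup `compositions`
#'   (rows named `C<class>.S<subgroup>`) updated.
#' @export
make_separable <- function(spec, divergence) {
  stopifnot(inherits(spec, "synthetic_spec"), divergence >= 0)
  spec$divergence <- divergence
  C <- spec$n_classes
  S <- spec$subgroups_per_class
  G <- C * S
  pos_all <- if (G == 1) 0 else seq(-1, 1, length.out = G)
  direction <- c(A = 1, C = -1, G = 1, T = -1)
  comps <- matrix(NA_real_, G, 4,
                  dimnames = list(character(G), c("A", "C", "G", "T")))
  clipped <- FALSE
  row <- 0
  for (s in seq_len(S)) {
    for (cl in seq_len(C)) {
      row <- row + 1
      # position index: consecutive positions alternate classes
      j <- (s - 1) * C + cl
      p <- spec$base_composition * (1 + divergence * pos_all[j] * direction)
      if (any(p < 0.01)) {
        clipped <- TRUE
        p <- pmax(p, 0.01)
      }
      comps[row, ] <- p / sum(p)
      rownames(comps)[row] <- sprintf("C%d.S%d", cl, s)
    }
  }
  if (clipped) {
    warning("divergence pushed probabilities out of the simplex; ",
            "clipped at 0.01 and renormalized")
  }
  spec$compositions <- comps
  spec
}

#' Generate a synthetic labelled dataset
#'
#' Draws i.i.d. multinomial sequences from each subgroup's composition.
#' The observed label is the subgroup's parent class; the hidden subgroup
#' ids are returned separately for cluster-recovery checks. Fully
#' deterministic per seed.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `dataset` (a `labeled_dataset`) and `subgroups`
#'   (named character vector, record id -> subgroup id `C<k>.S<j>`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (any(spec$compositions < 0) ||
      any(abs(rowSums(spec$compositions) - 1) > 1e-8)) {
    stop("invalid subgroup compositions")
  }
  set.seed(stage_seed(spec$seed, 0))
  bases <- c("A", "C", "G", "T")
  ids <- character(0)
  seqs <- character(0)
  labels <- character(0)
  subgroups <- character(0)
  for (g in rownames(spec$compositions)) {
    cl <- sub("\\.S\\d+$", "", g)
    for (i in seq_len(spec$samples_per_subgroup)) {
      id <- sprintf("%s.r%03d", g, i)
      ids <- c(ids, id)
      seqs <- c(seqs, paste(sample(bases, spec$sequence_length,
                                   replace = TRUE,
                                   prob = spec$compositions[g, ]),
                            collapse = ""))
      labels <- c(labels, cl)
      subgroups <- c(subgroups, g)
    }
  }
  records <- seq_records(ids, ids, seqs)
  list(dataset = labeled_dataset(records, setNames(labels, ids)),
       subgroups = setNames(subgroups, ids))
}

#' Write a synthetic dataset as loadable fixture files
#'
#' Emits `sequences.fasta`, `labels.tsv` (id, label) and `truth.json`
#' (spec parameters, compositions and hidden subgroup ids), all readable
#' by [read_fasta()] / [read_labels()] / `jsonlite`.
#'
#' @param spec A `synthetic_spec`.
#' @param directory Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(spec, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_dataset(spec)
  fasta <- file.path(directory, "sequences.fasta")
  labels <- file.path(directory, "labels.tsv")
  truth <- file.path(directory, "truth.json")
  write_fasta(gen$dataset$records, fasta)
  utils::write.table(
    data.frame(id = names(gen$dataset$labels),
               label = unname(gen$dataset$labels)),
    labels, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_classes = spec$n_classes,
         subgroups_per_class = spec$subgroups_per_class,
         samples_per_subgroup = spec$samples_per_subgroup,
         sequence_length = spec$sequence_length,
         divergence = spec$divergence,
         seed = spec$seed,
         compositions = as.data.frame(spec$compositions),
         subgroup_names = rownames(spec$compositions),
         subgroups = as.list(gen$subgroups)),
    truth, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta, labels = labels, truth = truth))
}
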