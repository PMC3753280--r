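# Feature extraction for the junction classifier. The committed feature set
# covers loop lengths, pairwise loop-length contrasts, per-loop base
# composition and purine fraction, closing-pair identities, helix lengths,
# and total loop size; dimensionality is fixed for a given degree.

closing_pair_code <- function(cp) {
  code <- match(cp, CANONICAL_PAIRS)
  code[is.na(code)] <- 0L
  code
}

#' Assemble the classifier feature vector
#'
#' Low-level constructor used by [extract_features()]; exposed so tabulated
#' junction records (without a parsed structure) can be featurized too.
#'
#' @param loop_seqs Character vector of loop sequences, `""` for empty loops.
#' @param helix_bp Integer vector of helix base-pair counts.
#' @param closing_pairs Character vector of loop-facing closing-pair letters
#'   per helix (e.g. `"GC"`).
#' @return Named numeric vector; identical input always yields an identical
#'   vector.
#' @export
feature_vector <- function(loop_seqs, helix_bp, closing_pairs) {
  n <- length(loop_seqs)
  stopifnot(length(helix_bp) == n, length(closing_pairs) == n)
  L <- nchar(loop_seqs)
  feats <- stats::setNames(as.numeric(L), paste0("L", seq_len(n)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    denom <- L[i] + L[j]
    feats[paste0("r", i, j)] <- if (denom > 0) (L[i] - L[j]) / denom else 0
  }
  for (i in seq_len(n)) {
    ch <- strsplit(loop_seqs[i], "")[[1]]
    for (b in c("A", "C", "G", "U")) {
      feats[paste0(b, i)] <- if (L[i] > 0) sum(ch == b) / L[i] else 0
    }
    feats[paste0("pur", i)] <-
      if (L[i] > 0) sum(ch %in% c("A", "G")) / L[i] else 0
  }
  feats[paste0("cp", seq_len(n))] <- closing_pair_code(closing_pairs)
  feats[paste0("bp", seq_len(n))] <- as.numeric(helix_bp)
  feats["totL"] <- sum(L)
  feats
}

#' Extract classifier features from a junction
#'
#' @param j An `rna_junction` (from [find_junctions()]) or a single-row
#'   junction record from a [junction_dataset].
#' @return Named numeric vector (deterministic for a given junction).
#' @export
extract_features <- function(j) UseMethod("extract_features")

#' @export
extract_features.rna_junction <- function(j) {
  if (!j$degree %in% c(3L, 4L))
    stop("unsupported junction degree: ", j$degree,
         " (only 3- and 4-way junctions are classified)")
  feature_vector(vapply(j$loops, `[[`, "", "seq"),
                 j$helices$bp, j$helices$closing_pair)
}

#' @export
extract_features.data.frame <- function(j) {
  if (nrow(j) != 1L) stop("expected a single record")
  feature_vector(split_field(j$loop_seqs, character = TRUE),
                 split_field(j$helix_bp),
                 split_field(j$closing_pairs, character = TRUE))
}

split_field <- function(x, character = FALSE) {
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  parts[parts == "-"] <- ""
  if (character) parts else as.integer(parts)
}

dataset_features <- function(data) {
  t(vapply(seq_len(nrow(data)),
           function(k) extract_features(data[k, , drop = FALSE]),
           extract_features(data[1L, , drop = FALSE])))
}
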