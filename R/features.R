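#' Fit a GO vocabulary on training records
#'
#' The vocabulary is the lexicographically sorted union of GO identifiers
#' over the supplied (training) records. It must be refit inside every
#' cross-validation training fold so the encoding never sees held-out data;
#' an empty union yields a valid size-0 vocabulary.
#'
#' @param training_records List of [protein_record()]s.
#' @return An object of class `go_vocabulary` with fields `terms`, `index`
#'   and `size`.
#' @export
fit_go_vocabulary <- function(training_records) {
  terms <- sort(unique(unlist(lapply(training_records, `[[`, "go_terms"))))
  if (is.null(terms)) terms <- character(0)
  structure(
    list(terms = terms,
         index = stats::setNames(seq_along(terms), terms),
         size = length(terms)),
    class = "go_vocabulary"
  )
}

#' Encode a protein's GO annotations as a binary vector
#'
#' Position i is 1 iff the vocabulary's i-th term annotates the protein.
#' Terms outside the vocabulary are ignored; a protein without annotations
#' encodes to the all-zero vector, so prediction still works when GO terms
#' are unavailable.
#'
#' @param record A [protein_record()] (or a character vector of GO ids).
#' @param vocab A fitted [fit_go_vocabulary()].
#' @return Integer 0/1 vector of length `vocab$size`.
#' @export
encode_go <- function(record, vocab) {
  terms <- if (inherits(record, "protein_record")) record$go_terms else record
  as.integer(vocab$terms %in% terms)
}

#' Concatenate a pooled embedding and a GO vector
#'
#' The combined protein representation: embedding block first (positions
#' 1..D), GO block second (positions D+1..D+V). The block order is fixed so
#' selection-mask indices stay portable.
#'
#' @param Fpr Numeric pooled-embedding vector (optionally carrying a
#'   `protein_id` attribute).
#' @param GOpr Binary GO vector (optionally carrying a `protein_id`
#'   attribute).
#' @return Numeric vector of length `D + V`.
#' @export
concat_representation <- function(Fpr, GOpr) {
  id_f <- attr(Fpr, "protein_id")
  id_g <- attr(GOpr, "protein_id")
  if (!is.null(id_f) && !is.null(id_g) && !identical(id_f, id_g)) {
    stopf("protein id mismatch: '%s' vs '%s'", id_f, id_g)
  }
  out <- c(as.numeric(Fpr), as.numeric(GOpr))
  attr(out, "protein_id") <- id_f %||% id_g
  attr(out, "block_sizes") <- c(embedding = length(Fpr), go = length(GOpr))
  out
}

#' Build the representation matrix for a set of records
#'
#' Rows are proteins; columns are the D embedding dimensions followed by the
#' V vocabulary terms. The `blocks` attribute records the column indices of
#' the embedding block and of the GO block.
#'
#' @param records List of [protein_record()]s.
#' @param embeddings Pooled-embedding matrix with rownames = protein ids
#'   (e.g. from [embed_proteins()] or a cache).
#' @param vocab A fitted [fit_go_vocabulary()].
#' @return Numeric matrix `n x (D + V)` with rownames = ids.
#' @export
build_representation <- function(records, embeddings, vocab) {
  ids <- vapply(records, `[[`, character(1), "id")
  missing <- setdiff(ids, rownames(embeddings))
  if (length(missing)) stopf("no embedding for protein '%s'", missing[1])
  emb <- embeddings[ids, , drop = FALSE]
  D <- ncol(emb)
  go <- if (vocab$size == 0L) {
    matrix(0L, nrow = length(records), ncol = 0L)
  } else {
    do.call(rbind, lapply(records, encode_go, vocab = vocab))
  }
  X <- cbind(emb, go)
  colnames(X) <- c(paste0("emb_", seq_len(D)), vocab$terms)
  rownames(X) <- ids
  attr(X, "blocks") <- list(embedding = seq_len(D),
                            go = if (vocab$size) D + seq_len(vocab$size) else integer(0))
  X
}

#' Amino-acid composition
#'
#' Frequencies of the 20 standard residues among the standard residues of
#' the sequence; extended letters (B, J, O, U, X, Z) are excluded from both
#' numerator and denominator.
#'
#' @param sequence Amino-acid string.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
compute_aac <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  std <- chars[chars %in% STANDARD_AA]
  if (length(std) == 0L) stopf("sequence has no standard residues")
  counts <- table(factor(std, levels = STANDARD_AA))
  stats::setNames(as.numeric(counts) / length(std), STANDARD_AA)
}
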