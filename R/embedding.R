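#' Embedder configuration
#'
#' Settings for producing per-residue embedding matrices. The `pretrained`
#' backend names a large protein language model checkpoint (default: the
#' 650M-parameter ESM-2 model, hidden layer 33, 1280 dimensions) and is only
#' usable where that model is installed; the `synthetic` backend is a fully
#' deterministic seeded-hash embedder used for simulation and testing, with
#' a configurable dimension.
#'
#' @param backend `"synthetic"` or `"pretrained"`.
#' @param checkpoint_id Pretrained checkpoint identifier.
#' @param layer_index Hidden layer whose activations are used (pretrained).
#' @param dim Embedding dimension D.
#' @param max_tokens Sequences longer than this are truncated to their
#'   N-terminal `max_tokens` residues before embedding (default 1024).
#' @param seed Seed for the synthetic backend's hash expansion.
#' @param kmer_window Neighborhood width used by the synthetic backend: each
#'   residue is embedded from the k-mer centred on it.
#' @return An object of class `embedder_config`.
#' @export
embedder_config <- function(backend = c("synthetic", "pretrained"),
                            checkpoint_id = "esm2_t33_650M_UR50D",
                            layer_index = 33L, dim = 1280L,
                            max_tokens = 1024L, seed = 1L,
                            kmer_window = 3L) {
  backend <- match.arg(backend)
  if (dim < 1L) stopf("dim must be >= 1")
  if (max_tokens < 1L) stopf("max_tokens must be >= 1")
  if (layer_index < 0L) stopf("layer_index must be >= 0")
  structure(
    list(backend = backend, checkpoint_id = checkpoint_id,
         layer_index = as.integer(layer_index), dim = as.integer(dim),
         max_tokens = as.integer(max_tokens), seed = as.integer(seed),
         kmer_window = as.integer(kmer_window)),
    class = "embedder_config"
  )
}

#' Truncate a sequence to a token budget
#'
#' Keeps the N-terminal prefix of length `min(L, max_tokens)`; the result is
#' never empty.
#'
#' @param sequence Amino-acid string.
#' @param max_tokens Maximum number of residues kept.
#' @return The (possibly truncated) sequence.
#' @export
truncate_sequence <- function(sequence, max_tokens = 1024L) {
  if (max_tokens < 1L) stopf("max_tokens must be >= 1")
  if (nchar(sequence) < 1L) stopf("sequence is empty")
  substr(sequence, 1L, min(nchar(sequence), max_tokens))
}

# Polynomial string hash on a 31-bit field; the basis of the synthetic
# backend's determinism.
hash_string <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  h
}

# One embedding vector per k-mer: a seeded standard-normal expansion, so
# each dimension has zero mean and unit variance over the k-mer alphabet.
kmer_vector <- function(kmer, dim, seed) {
  set.seed(as.integer((hash_string(kmer) + 7919 * as.double(seed)) %% 2147483647))
  stats::rnorm(dim)
}

#' Embed the residues of one sequence
#'
#' Returns a matrix with one row per residue of the (internally truncated)
#' sequence and `config$dim` columns. The synthetic backend maps residue i to
#' a seeded-hash expansion of the k-mer centred on it, so the output is
#' bit-identical for identical `(sequence, seed, dim, kmer_window)`. A
#' pretrained backend would exclude its begin/end special tokens from the
#' returned matrix; it is config-gated and unavailable offline.
#'
#' @param sequence Amino-acid string.
#' @param config An [embedder_config()].
#' @return Numeric matrix of shape `L' x dim` with `L' = min(L, max_tokens)`.
#' @export
embed_residues <- function(sequence, config = embedder_config()) {
  if (config$backend == "pretrained") {
    stopf(paste("pretrained checkpoint '%s' is not available in this",
                "installation; use embedder_config(backend = 'synthetic')",
                "for offline work"), config$checkpoint_id)
  }
  sequence <- truncate_sequence(toupper(sequence), config$max_tokens)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  half <- config$kmer_window %/% 2L
  F <- matrix(0, nrow = L, ncol = config$dim)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(L)) {
    kmer <- paste(chars[max(1L, i - half):min(L, i + half)], collapse = "")
    v <- cache[[kmer]]
    if (is.null(v)) {
      v <- kmer_vector(kmer, config$dim, config$seed)
      cache[[kmer]] <- v
    }
    F[i, ] <- v
  }
  F
}

#' Mean-pool a residue embedding matrix
#'
#' The per-protein representation is the unweighted arithmetic mean of the
#' per-residue embedding vectors (the rows of `F`).
#'
#' @param F Numeric matrix, one row per residue.
#' @return Numeric vector of length `ncol(F)`.
#' @export
mean_pool <- function(F) {
  F <- as.matrix(F)
  if (nrow(F) < 1L) stopf("cannot pool an empty embedding matrix")
  if (!all(is.finite(F))) stopf("non-finite value in embedding matrix")
  colMeans(F)
}

#' Pooled embeddings for a set of records
#'
#' Convenience wrapper: embeds and mean-pools every record, sharing the
#' k-mer cache across proteins. RNG state of the caller is left untouched.
#'
#' @param records List of [protein_record()]s.
#' @param config An [embedder_config()].
#' @return Numeric matrix, one row per record (rownames = ids), `dim` columns.
#' @export
embed_proteins <- function(records, config = embedder_config()) {
  with_local_seed(config$seed, {
    mat <- t(vapply(records, function(r) mean_pool(embed_residues(r$sequence, config)),
                    numeric(config$dim)))
    rownames(mat) <- vapply(records, `[[`, character(1), "id")
    mat
  })
}

#' Read/write a pooled-embedding cache
#'
#' Tab-separated values (id column + one column per dimension) with a JSON
#' sidecar (`<path>.json`) recording backend, checkpoint, layer and
#' dimension, so a cache is never silently reused across embedders.
#'
#' @param embeddings Numeric matrix with rownames = protein ids.
#' @param path Output TSV path.
#' @param config The [embedder_config()] that produced the matrix.
#' @return `path`, invisibly.
#' @export
write_embedding_cache <- function(embeddings, path, config) {
  df <- data.frame(id = rownames(embeddings), embeddings,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", paste0("d", seq_len(ncol(embeddings))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(backend = config$backend, checkpoint_id = config$checkpoint_id,
         layer_index = config$layer_index, dim = config$dim,
         max_tokens = config$max_tokens, kmer_window = config$kmer_window,
         seed = config$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_embedding_cache
#' @export
read_embedding_cache <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$id
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(mat, "embedder") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  mat
}
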