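#' Simulation configuration
#'
#' Defaults define the standard synthetic study conditions used throughout
#' the package's tests: a balanced two-class set of 600 proteins (300 drug
#' targets, 300 non-targets), 64 embedding dimensions of which 10 carry a
#' class-dependent mean shift of 3 pooled-embedding SDs, and a 40-term GO
#' universe with 8 terms enriched in the positive class (presence 0.6 vs
#' 0.3) over a 5% background annotation rate. Sequence lengths are uniform
#' on 50-200 residues.
#'
#' @param n_pos,n_neg Class sizes.
#' @param seq_length_range Min/max sequence length.
#' @param embed_dim Embedding dimension D of the synthetic backend.
#' @param n_informative Number of embedding dimensions carrying class signal.
#' @param effect_size Mean shift on informative dimensions, in units of the
#'   per-dimension SD of the pooled embeddings (0 = exchangeable classes).
#' @param n_go_terms Size of the simulated GO universe.
#' @param n_enriched_go Number of class-enriched GO terms.
#' @param go_prob_pos,go_prob_neg Presence probability of an enriched term
#'   in positives / negatives.
#' @param background_go_prob Presence probability of every other term.
#' @param seed Master seed; every artifact uses a named derived substream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pos = 300L, n_neg = 300L,
                       seq_length_range = c(50L, 200L),
                       embed_dim = 64L, n_informative = 10L, effect_size = 3,
                       n_go_terms = 40L, n_enriched_go = 8L,
                       go_prob_pos = 0.6, go_prob_neg = 0.3,
                       background_go_prob = 0.05, seed = 1L) {
  probs <- c(go_prob_pos, go_prob_neg, background_go_prob)
  if (any(probs < 0 | probs > 1)) stopf("GO probabilities must be in [0, 1]")
  if (n_informative < 0L || n_informative > embed_dim) {
    stopf("n_informative must be in [0, embed_dim]")
  }
  if (n_pos < 1L || n_neg < 1L) stopf("both classes need at least one protein")
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         seq_length_range = as.integer(seq_length_range),
         embed_dim = as.integer(embed_dim),
         n_informative = as.integer(n_informative), effect_size = effect_size,
         n_go_terms = as.integer(n_go_terms),
         n_enriched_go = as.integer(n_enriched_go),
         go_prob_pos = go_prob_pos, go_prob_neg = go_prob_neg,
         background_go_prob = background_go_prob, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate a labeled synthetic dataset
#'
#' Emulates the statistical structure the pipeline assumes: random
#' sequences over the 20-letter alphabet, pooled synthetic-backend
#' embeddings with a class-dependent mean shift injected on the designated
#' informative dimensions (at the embedding-cache level, so downstream
#' stages are agnostic to its origin), and GO annotations with
#' class-enriched terms. Simulated GO terms are assigned cyclically to the
#' three sub-ontologies (MF, CC, BP). Fully reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @return A [druggability_dataset()]; attributes `informative_dims`,
#'   `enriched_terms` and `sim_config` record the ground truth.
#' @export
generate_dataset <- function(config = sim_config()) {
  n <- config$n_pos + config$n_neg
  labels <- c(rep(1L, config$n_pos), rep(0L, config$n_neg))
  ids <- sprintf("SP%05d", seq_len(n))

  sequences <- with_local_seed(derive_seed(config$seed, "sequences"), {
    lens <- sample(config$seq_length_range[1]:config$seq_length_range[2],
                   n, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(STANDARD_AA, L, replace = TRUE), collapse = "")
    }, character(1))
  })

  go_terms_all <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  enriched <- go_terms_all[seq_len(config$n_enriched_go)]
  namespaces <- stats::setNames(rep(c("MF", "CC", "BP"),
                                    length.out = config$n_go_terms),
                                go_terms_all)
  go_sets <- with_local_seed(derive_seed(config$seed, "go"), {
    lapply(seq_len(n), function(i) {
      p <- ifelse(go_terms_all %in% enriched,
                  if (labels[i] == 1L) config$go_prob_pos else config$go_prob_neg,
                  config$background_go_prob)
      go_terms_all[stats::runif(config$n_go_terms) < p]
    })
  })

  records <- lapply(seq_len(n), function(i) {
    protein_record(ids[i], sequences[i], go_terms = go_sets[[i]],
                   label = labels[i])
  })

  emb_cfg <- embedder_config(backend = "synthetic", dim = config$embed_dim,
                             seed = derive_seed(config$seed, "embedder"))
  emb <- embed_proteins(records, emb_cfg)
  informative <- seq_len(config$n_informative)
  if (config$n_informative > 0L && config$effect_size != 0) {
    sds <- apply(emb[, informative, drop = FALSE], 2, stats::sd)
    shift <- config$effect_size * sds
    emb[labels == 1L, informative] <-
      sweep(emb[labels == 1L, informative, drop = FALSE], 2, shift, "+")
  }

  data <- druggability_dataset(records, emb, go_namespaces = namespaces)
  attr(data, "informative_dims") <- informative
  attr(data, "enriched_terms") <- enriched
  attr(data, "sim_config") <- config
  attr(data, "embedder_config") <- emb_cfg
  data
}

#' Write a dataset to disk in the pipeline's input formats
#'
#' FASTA sequences, two-column TSV GO annotations, a CSV manifest
#' (id,label,split) and a TSV + JSON embedding cache -- exactly the formats
#' the real pipeline ingests, so a simulated run exercises the same I/O
#' paths. Byte-identical across runs with the same config.
#'
#' @param data A [druggability_dataset()] (typically [generate_dataset()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(data$records, file.path(dir, "sequences.fasta"))
  rows <- unlist(lapply(data$records, function(r) {
    if (length(r$go_terms)) paste(r$id, sort(r$go_terms), sep = "\t")
  }))
  writeLines(rows %||% character(0), file.path(dir, "annotations.tsv"))
  write_manifest(data.frame(id = dataset_ids(data),
                            label = dataset_labels(data),
                            split = NA_character_),
                 file.path(dir, "manifest.csv"))
  emb_cfg <- attr(data, "embedder_config") %||% embedder_config(
    backend = "synthetic", dim = ncol(data$embeddings))
  write_embedding_cache(data$embeddings, file.path(dir, "embeddings.tsv"), emb_cfg)
  if (!is.null(data$go_namespaces)) {
    utils::write.table(
      data.frame(go_id = names(data$go_namespaces),
                 namespace = unname(data$go_namespaces)),
      file.path(dir, "go_namespaces.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Load a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A [druggability_dataset()].
#' @export
read_dataset <- function(dir) {
  records <- read_fasta(file.path(dir, "sequences.fasta"))
  ann_path <- file.path(dir, "annotations.tsv")
  annotations <- if (file.exists(ann_path) && file.size(ann_path) > 0) {
    read_go_annotations(ann_path, "tsv")
  } else {
    list()
  }
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  labels <- stats::setNames(manifest$label, manifest$id)
  records <- lapply(records, function(r) {
    r$go_terms <- annotations[[r$id]] %||% character(0)
    lab <- labels[[r$id]]
    r$label <- if (is.null(lab) || is.na(lab)) NA_integer_ else as.integer(lab)
    r
  })
  emb <- read_embedding_cache(file.path(dir, "embeddings.tsv"))
  ns_path <- file.path(dir, "go_namespaces.tsv")
  ns <- NULL
  if (file.exists(ns_path)) {
    df <- utils::read.delim(ns_path, stringsAsFactors = FALSE)
    ns <- stats::setNames(df$namespace, df$go_id)
  }
  druggability_dataset(records, emb, go_namespaces = ns)
}

#' Generate a toy alpha-carbon trace
#'
#' A self-avoiding random walk with consecutive CA-CA steps of exactly
#' 3.8 Angstrom (idealized backbone spacing) and a minimum non-consecutive
#' separation of 4.0 Angstrom enforced by rejection, for exercising the
#' structure representations on realistic-scale geometry.
#'
#' @param n_residues Chain length.
#' @param seed Seed for the walk.
#' @param step Consecutive CA-CA distance (Angstrom).
#' @param min_separation Minimum allowed non-consecutive distance.
#' @param max_tries Per-residue rejection budget before restarting; the
#'   generator errors after `max_tries` full restarts.
#' @param path Optional path: when given, the trace is also written as a
#'   single-chain PDB file that [read_pdb_monomer()] round-trips.
#' @return A [structure_record()].
#' @export
generate_toy_structure <- function(n_residues, seed = 1L, step = 3.8,
                                   min_separation = 4.0, max_tries = 200L,
                                   path = NULL) {
  if (n_residues < 1L) stopf("n_residues must be >= 1")
  coords <- with_local_seed(seed, {
    result <- NULL
    for (restart in seq_len(max_tries)) {
      xyz <- matrix(0, nrow = n_residues, ncol = 3L)
      ok <- TRUE
      for (i in seq_len(n_residues)[-1]) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          u <- stats::rnorm(3)
          cand <- xyz[i - 1L, ] + step * u / sqrt(sum(u^2))
          if (i > 2L) {
            d2 <- rowSums(sweep(xyz[seq_len(i - 2L), , drop = FALSE], 2, cand)^2)
            if (min(d2) < min_separation^2) next
          }
          xyz[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) { result <- xyz; break }
    }
    if (is.null(result)) {
      stopf("self-avoiding walk rejection budget exceeded; try fewer residues")
    }
    result
  })
  if (!is.null(path)) write_pdb_ca(coords, path)
  structure_record(id = sprintf("toy_%d", seed), chain_id = "A",
                   ca_coords = coords)
}
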