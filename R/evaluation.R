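METRIC_NAMES <- c("auc", "auprc", "precision", "recall", "accuracy",
                  "specificity", "npv", "f1", "mcc", "kappa", "dor", "dp",
                  "dkl")

#' Full metrics report for a scored set
#'
#' The thirteen-metric battery: AUC, AUPRC, precision, recall, accuracy,
#' specificity, NPV, F1, MCC, Cohen's kappa, diagnostic odds ratio,
#' discriminant power and the Bernoulli KL divergence of prevalence versus
#' mean score.
#'
#' @param scores Numeric scores in [0, 1].
#' @param labels Binary labels (0/1), both classes present.
#' @param threshold Decision threshold for the confusion-based metrics.
#' @return Named list of the 13 metrics plus `n` and `threshold`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  cls <- classification_metrics(confusion(scores, labels, threshold))
  rnk <- ranking_metrics(scores, labels)
  c(list(auc = rnk$auc, auprc = rnk$auprc),
    cls[c("precision", "recall", "accuracy", "specificity", "npv", "f1",
          "mcc", "kappa", "dor", "dp")],
    list(dkl = dkl(labels, scores), n = length(labels), threshold = threshold))
}

# Stratified fold assignment: within each class, a seeded shuffle is dealt
# round-robin over folds, so class balance is as even as integer counts allow.
make_folds <- function(y, folds, seed) {
  assignment <- integer(length(y))
  with_local_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      assignment[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

dataset_labels <- function(data) {
  vapply(data$records, `[[`, integer(1), "label")
}

dataset_ids <- function(data) {
  vapply(data$records, `[[`, character(1), "id")
}

#' Assemble a druggability dataset
#'
#' Bundles protein records with their pooled embeddings (and, optionally, a
#' GO-term to sub-ontology namespace map used by the JM report).
#'
#' @param records List of [protein_record()]s.
#' @param embeddings Pooled-embedding matrix, rownames = protein ids.
#' @param go_namespaces Optional named character vector mapping GO ids to
#'   namespaces (`"MF"`, `"CC"`, `"BP"`).
#' @return An object of class `druggability_dataset`.
#' @export
druggability_dataset <- function(records, embeddings, go_namespaces = NULL) {
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stopf("duplicate record id: '%s'", ids[duplicated(ids)][1])
  missing <- setdiff(ids, rownames(embeddings))
  if (length(missing)) stopf("no embedding for protein '%s'", missing[1])
  structure(list(records = records, embeddings = embeddings,
                 go_namespaces = go_namespaces),
            class = "druggability_dataset")
}

#' Fit the full druggability pipeline on labeled data
#'
#' Fits, in order and on the supplied data only: the GO vocabulary, the
#' standardizing SVM-weight selection mask, and the neural head. The three
#' fitted objects travel together so prediction replays exactly the
#' training-time transform.
#'
#' @param data A [druggability_dataset()] with labels on every record.
#' @param k Number of features kept by the selector.
#' @param dnn A [dnn_config()].
#' @param selector_cost Soft-margin cost of the selection SVM.
#' @return An object of class `druggability_model` with `vocab`, `mask`,
#'   `dnn` and dimensions.
#' @export
fit_druggability <- function(data, k = 4000L, dnn = dnn_config(),
                             selector_cost = 1) {
  y <- dataset_labels(data)
  if (anyNA(y)) stopf("all records must be labeled for fitting")
  vocab <- fit_go_vocabulary(data$records)
  X <- build_representation(data$records, data$embeddings, vocab)
  mask <- fit_selector(X, y, k = min(k, ncol(X)), cost = selector_cost)
  model <- dnn_train(apply_mask(X, mask), y, dnn)
  structure(
    list(vocab = vocab, mask = mask, dnn = model,
         embed_dim = ncol(data$embeddings), k = mask$k),
    class = "druggability_model"
  )
}

#' Predict druggability scores
#'
#' @param model A [fit_druggability()] result.
#' @param data A [druggability_dataset()] (labels not required or used).
#' @return Named numeric vector of scores in [0, 1].
#' @export
predict_druggability <- function(model, data) {
  X <- build_representation(data$records, data$embeddings, model$vocab)
  scores <- dnn_predict(model$dnn, apply_mask(X, model$mask))
  stats::setNames(scores, dataset_ids(data))
}

#' Save / load a fitted pipeline bundle
#'
#' The bundle directory holds the serialized fitted objects plus a JSON
#' metadata file (k, dimensions, vocabulary hash); save then load then
#' predict reproduces the pre-save scores bit for bit.
#'
#' @param model A `druggability_model`.
#' @param dir Bundle directory (created if needed).
#' @return `dir` invisibly; `load_druggability_model` returns the model.
#' @export
save_druggability_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(
    list(k = model$k, embed_dim = model$embed_dim,
         vocab_size = model$vocab$size,
         vocab_hash = hash_string(paste(model$vocab$terms, collapse = ","))),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_druggability_model
#' @export
load_druggability_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}

#' Leak-free repeated stratified cross-validation
#'
#' For each of `runs` independent repetitions, records are dealt into
#' `folds` stratified folds (seeded). Within every fold, the GO vocabulary,
#' the feature standardization, the SVM selection mask and the neural head
#' are fitted on the training folds only, then the held-out fold is scored
#' and the full metric battery computed. Results are aggregated as mean,
#' SD and a t-distribution 95% confidence interval over all fold-level
#' values.
#'
#' @param data A labeled [druggability_dataset()].
#' @param folds Number of folds (default 10).
#' @param runs Number of independent repetitions (default 5).
#' @param k Features kept by the selector (default 4000, capped at p).
#' @param dnn A [dnn_config()]; its seed is re-derived per run and fold.
#' @param threshold Decision threshold.
#' @param seed Master seed for fold assignment and per-fold training.
#' @return An object of class `cv_result`: `per_fold` (data.frame of
#'   fold-level metrics), `summary` (mean/sd/ci per metric), and the
#'   settings.
#' @export
cross_validate <- function(data, folds = 10L, runs = 5L, k = 4000L,
                           dnn = dnn_config(), threshold = 0.5, seed = 1L) {
  y <- dataset_labels(data)
  if (anyNA(y)) stopf("all records must be labeled for cross-validation")
  rows <- list()
  for (run in seq_len(runs)) {
    fold_of <- make_folds(y, folds, derive_seed(seed, "folds", run))
    for (fold in seq_len(folds)) {
      tr <- which(fold_of != fold)
      te <- which(fold_of == fold)
      if (length(unique(y[tr])) < 2L) {
        stopf("class absent from the training folds (run %d fold %d)", run, fold)
      }
      train_data <- druggability_dataset(data$records[tr],
                                         data$embeddings,
                                         data$go_namespaces)
      dnn_fold <- dnn
      dnn_fold$seed <- derive_seed(seed, "dnn", run, fold)
      model <- fit_druggability(train_data, k = k, dnn = dnn_fold)
      test_data <- druggability_dataset(data$records[te], data$embeddings,
                                        data$go_namespaces)
      scores <- predict_druggability(model, test_data)
      rep <- evaluate_scores(scores, y[te], threshold)
      rows[[length(rows) + 1L]] <-
        data.frame(run = run, fold = fold,
                   as.data.frame(rep[METRIC_NAMES]), n = rep$n)
    }
  }
  per_fold <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(METRIC_NAMES, function(m) {
    v <- per_fold[[m]]
    v <- v[is.finite(v)]
    mn <- mean(v); s <- stats::sd(v)
    half <- if (length(v) > 1L) stats::qt(0.975, length(v) - 1L) * s / sqrt(length(v)) else NA_real_
    data.frame(metric = m, mean = mn, sd = s,
               ci_lower = mn - half, ci_upper = mn + half, n_folds = length(v))
  }))
  structure(list(per_fold = per_fold, summary = summary, folds = folds,
                 runs = runs, k = k, threshold = threshold, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation: %d runs x %d folds (k = %d)\n",
              x$runs, x$folds, x$k))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %6.3f +/- %.3f  [%.3f, %.3f]\n", s$metric[i],
                s$mean[i], s$sd[i], s$ci_lower[i], s$ci_upper[i]))
  }
  invisible(x)
}

#' Random-label null check
#'
#' Relabels the dataset `reps` times from a binomial with success
#' probability equal to the observed prevalence (features untouched), runs
#' the full cross-validation on each relabeling, and returns the resulting
#' `cv_result`s. A sound, leak-free pipeline scores at chance on every
#' relabeling while the real labels stand far above it.
#'
#' @param data A labeled [druggability_dataset()].
#' @param reps Number of relabelings (default 5).
#' @param seed Master seed.
#' @inheritParams cross_validate
#' @return List of `reps` [cross_validate()] results.
#' @export
random_label_null <- function(data, reps = 5L, folds = 10L, runs = 1L,
                              k = 4000L, dnn = dnn_config(), threshold = 0.5,
                              seed = 1L) {
  y <- dataset_labels(data)
  prevalence <- mean(y)
  lapply(seq_len(reps), function(rep) {
    y_null <- with_local_seed(derive_seed(seed, "null", rep),
                              stats::rbinom(length(y), 1L, prevalence))
    records <- mapply(function(r, lab) { r$label <- as.integer(lab); r },
                      data$records, y_null, SIMPLIFY = FALSE)
    null_data <- druggability_dataset(records, data$embeddings,
                                      data$go_namespaces)
    cross_validate(null_data, folds = folds, runs = runs, k = k, dnn = dnn,
                   threshold = threshold, seed = derive_seed(seed, "nullcv", rep))
  })
}

#' Independent-set evaluation
#'
#' Single fit on the full training set (vocabulary, mask, neural head),
#' single evaluation on a disjoint test set. Overlapping protein ids are an
#' error, not a warning.
#'
#' @param train_data,test_data Labeled [druggability_dataset()]s with
#'   disjoint id sets.
#' @inheritParams cross_validate
#' @return List with `metrics` (the 13-metric report), `scores` and the
#'   fitted `model`.
#' @export
independent_test <- function(train_data, test_data, k = 4000L,
                             dnn = dnn_config(), threshold = 0.5) {
  overlap <- intersect(dataset_ids(train_data), dataset_ids(test_data))
  if (length(overlap)) {
    stopf("train and test sets overlap: %s",
          paste(utils::head(overlap, 5), collapse = ", "))
  }
  model <- fit_druggability(train_data, k = k, dnn = dnn)
  scores <- predict_druggability(model, test_data)
  list(metrics = evaluate_scores(scores, dataset_labels(test_data), threshold),
       scores = scores, model = model)
}

#' JM separability report for a dataset
#'
#' JM distance of the embedding block and of the GO block(s) between the
#' two classes, computed on the concatenated representation with a
#' vocabulary fitted on the whole dataset. When the dataset carries GO
#' namespace assignments, the GO block is split per sub-ontology (MF, CC,
#' BP).
#'
#' @param data A labeled [druggability_dataset()].
#' @return Named numeric vector of JM distances per feature category.
#' @export
jm_report <- function(data) {
  y <- dataset_labels(data)
  vocab <- fit_go_vocabulary(data$records)
  X <- build_representation(data$records, data$embeddings, vocab)
  blocks <- attr(X, "blocks")
  out <- list(embedding = blocks$embedding)
  if (length(blocks$go)) {
    ns <- data$go_namespaces
    if (!is.null(ns)) {
      for (space in unique(ns[vocab$terms])) {
        cols <- blocks$go[which(ns[vocab$terms] == space)]
        if (length(cols)) out[[paste0("go_", space)]] <- cols
      }
    } else {
      out$go <- blocks$go
    }
  }
  jm_by_block(X, y, out)
}
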