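# Reduced problem sizes keep these end-to-end checks fast; the acceptance
# suite runs the larger study conditions.
FAST_DNN <- dnn_config(max_epochs = 10L, seed = 1L)

test_that("every record lands in exactly one test fold per run", {
  d <- small_signal_dataset(seed = 50, n_per_class = 30)
  res <- cross_validate(d, folds = 5, runs = 2, k = 20, dnn = FAST_DNN, seed = 2)
  counts <- with(res$per_fold, tapply(n, run, sum))
  expect_equal(as.vector(counts), rep(60, 2))
  expect_equal(nrow(res$per_fold), 10)
  expect_s3_class(res, "cv_result")
  expect_true(all(c("auc", "mcc", "dkl") %in% res$summary$metric))
})

test_that("cross-validation separates the default signal regime", {
  d <- small_signal_dataset(seed = 51, n_per_class = 100)
  res <- cross_validate(d, folds = 3, runs = 1, k = 40,
                        dnn = dnn_config(seed = 1L), seed = 3)
  auc <- res$summary$mean[res$summary$metric == "auc"]
  expect_gte(auc, 0.85)
})

test_that("fitting never touches held-out records", {
  d <- small_signal_dataset(seed = 52, n_per_class = 40)
  y <- vapply(d$records, `[[`, integer(1), "label")
  test_idx <- seq(1, 80, by = 4)
  train_records <- d$records[-test_idx]
  fit_once <- function(data) {
    vocab <- fit_go_vocabulary(data$records)
    X <- build_representation(data$records, data$embeddings, vocab)
    mask <- fit_selector(X, vapply(data$records, `[[`, integer(1), "label"),
                         k = 20)
    list(vocab = vocab, mask = mask)
  }
  base <- fit_once(druggability_dataset(train_records, d$embeddings))
  # corrupt the held-out embeddings and labels, refit: nothing may change
  emb2 <- d$embeddings
  emb2[test_idx, ] <- 1e6
  corrupted_records <- d$records
  for (i in test_idx) corrupted_records[[i]]$label <- 1L - corrupted_records[[i]]$label
  again <- fit_once(druggability_dataset(corrupted_records[-test_idx], emb2))
  expect_identical(base$vocab, again$vocab)
  expect_identical(base$mask$kept_indices, again$mask$kept_indices)
  expect_identical(base$mask$center, again$mask$center)
})

test_that("cross-validation errors when a training fold loses a class", {
  d <- small_signal_dataset(seed = 53, n_per_class = 2)
  expect_error(cross_validate(d, folds = 4, runs = 1, k = 5, dnn = FAST_DNN),
               "class absent|both classes|validation")
})

test_that("random-label nulls keep prevalence and return one report per rep", {
  d <- small_signal_dataset(seed = 54, n_per_class = 40)
  reps <- random_label_null(d, reps = 3, folds = 3, runs = 1, k = 15,
                            dnn = FAST_DNN, seed = 7)
  expect_length(reps, 3)
  for (r in reps) {
    expect_s3_class(r, "cv_result")
    auc <- r$summary$mean[r$summary$metric == "auc"]
    expect_gt(auc, 0.3)
    expect_lt(auc, 0.7)
  }
})

test_that("independent evaluation rejects id overlap and ignores test labels", {
  train <- small_signal_dataset(seed = 55, n_per_class = 50)
  test <- generate_dataset(sim_config(n_pos = 25, n_neg = 25, seed = 56))
  test$records <- lapply(test$records, function(r) {
    r$id <- paste0("IND_", r$id); r
  })
  rownames(test$embeddings) <- paste0("IND_", rownames(test$embeddings))
  out <- independent_test(train, test, k = 25, dnn = FAST_DNN)
  expect_gte(out$metrics$auc, 0.8)
  expect_error(independent_test(train, train, k = 25, dnn = FAST_DNN),
               "overlap")
  # relabeling the test set cannot change predicted scores
  flipped <- test
  flipped$records <- lapply(flipped$records, function(r) {
    r$label <- 1L - r$label; r
  })
  expect_identical(predict_druggability(out$model, flipped), out$scores)
})

test_that("independent-set performance tracks the cross-validated estimate", {
  train <- small_signal_dataset(seed = 57, n_per_class = 150)
  test <- generate_dataset(sim_config(n_pos = 40, n_neg = 40, seed = 58))
  test$records <- lapply(test$records, function(r) { r$id <- paste0("T", r$id); r })
  rownames(test$embeddings) <- paste0("T", rownames(test$embeddings))
  full <- dnn_config(seed = 1L)
  cv_auc <- cross_validate(train, folds = 3, runs = 1, k = 30, dnn = full,
                           seed = 4)$summary
  cv_auc <- cv_auc$mean[cv_auc$metric == "auc"]
  ind_auc <- independent_test(train, test, k = 30, dnn = full)$metrics$auc
  expect_lt(abs(cv_auc - ind_auc), 0.05)
})

test_that("the JM report covers the embedding and GO sub-ontology blocks", {
  d <- small_signal_dataset(seed = 59, n_per_class = 60)
  jm <- jm_report(d)
  expect_setequal(names(jm), c("embedding", "go_MF", "go_CC", "go_BP"))
  expect_true(all(jm >= 0 & jm <= sqrt(2)))
  expect_gt(jm["embedding"], 0.5)   # delta = 3 on 10 of 64 dims separates
})
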