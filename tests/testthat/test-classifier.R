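test_that("the learning-rate schedule starts at 2e-4, halves every 5 epochs and floors", {
  cfg <- dnn_config()
  expect_equal(lr_schedule(0, cfg), 2e-4)
  expect_equal(lr_schedule(7, cfg), 1e-4)
  expect_equal(lr_schedule(30, cfg), 2.5e-5)
  expect_equal(lr_schedule(0:40, cfg),
               pmax(2.5e-5, 2e-4 / 2^floor(0:40 / 5)))
})

test_that("training separates a linearly separable synthetic problem", {
  set.seed(20)
  d <- shifted_matrix(n_per_class = 300, p = 20, s = 20, delta = 3)
  holdout <- sample(600, 150)
  model <- dnn_train(d$X[-holdout, ], d$y[-holdout],
                     dnn_config(max_epochs = 30, seed = 1))
  scores <- dnn_predict(model, d$X[holdout, ])
  expect_gte(ranking_metrics(scores, d$y[holdout])$auc, 0.95)
})

test_that("permuted labels give chance-level held-out performance", {
  set.seed(21)
  d <- shifted_matrix(n_per_class = 300, p = 20, s = 20, delta = 3)
  y_perm <- sample(d$y)
  holdout <- sample(600, 150)
  model <- dnn_train(d$X[-holdout, ], y_perm[-holdout],
                     dnn_config(max_epochs = 15, seed = 2))
  scores <- dnn_predict(model, d$X[holdout, ])
  auc <- ranking_metrics(scores, y_perm[holdout])$auc
  expect_gte(auc, 0.40)
  expect_lte(auc, 0.60)
})

test_that("training is fully seeded and history is well-formed", {
  set.seed(22)
  d <- shifted_matrix(60, 8, 4, 2)
  cfg <- dnn_config(max_epochs = 8, seed = 9)
  m1 <- dnn_train(d$X, d$y, cfg)
  m2 <- dnn_train(d$X, d$y, cfg)
  expect_identical(m1$params, m2$params)
  expect_true(all(is.finite(m1$history$train_loss)))
  expect_true(all(is.finite(m1$history$val_loss)))
  # early stopping never returns weights from after the best epoch
  expect_lte(m1$best_epoch, max(m1$history$epoch))
  expect_equal(m1$best_epoch,
               m1$history$epoch[which.min(m1$history$val_loss)])
})

test_that("scores are probabilities, pointwise and batch-size independent", {
  set.seed(23)
  d <- shifted_matrix(50, 6, 3, 2)
  model <- dnn_train(d$X, d$y, dnn_config(max_epochs = 5, seed = 3))
  scores <- dnn_predict(model, d$X)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_equal(dnn_predict(model, d$X[c(1, 1), ]),
               rep(dnn_predict(model, d$X[1, , drop = FALSE]), 2))
  one_by_one <- vapply(seq_len(10), function(i)
    dnn_predict(model, d$X[i, , drop = FALSE]), numeric(1))
  expect_equal(one_by_one, scores[1:10], tolerance = 1e-6)
  expect_error(dnn_predict(model, d$X[, 1:3]), "expects")
})

test_that("a fitted pipeline bundle predicts identically after save/load", {
  d <- small_signal_dataset(seed = 31, n_per_class = 40)
  model <- fit_druggability(d, k = 20, dnn = dnn_config(max_epochs = 5, seed = 4))
  scores <- predict_druggability(model, d)
  dir <- tempfile()
  save_druggability_model(model, dir)
  reloaded <- load_druggability_model(dir)
  expect_identical(predict_druggability(reloaded, d), scores)
})

test_that("the parameter count matches its closed form", {
  # closed form: sum over hidden layers of (in*out + out + 2*out), plus the
  # output unit (last_hidden + 1)
  expect_equal(n_dnn_parameters(4000), 4000 * 128 + 128 + 256 +
                 128 * 64 + 64 + 128 + 64 * 32 + 32 + 64 + 33)
  d <- shifted_matrix(30, 7, 3, 2)
  model <- dnn_train(d$X, d$y, dnn_config(hidden_units = c(8L, 4L),
                                          max_epochs = 2, seed = 5))
  counted <- sum(vapply(model$params$hidden, function(l)
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta), numeric(1))) +
    length(model$params$out$W) + 1
  expect_equal(counted, n_dnn_parameters(7, c(8L, 4L)))
})

test_that("with regularization off the head can memorize a small sample", {
  # 25 distinct points, each seen twice with a consistent arbitrary label:
  # zero Bayes error, so only capacity limits training accuracy.
  set.seed(24)
  Xu <- matrix(rnorm(25 * 10), 25, 10)
  yu <- rep(c(0, 1), length.out = 25)
  X <- rbind(Xu, Xu)
  y <- c(yu, yu)
  cfg <- dnn_config(dropout_rate = 0, l2_penalty = 0, lr_initial = 0.01,
                    lr_halving_every = 1000L, lr_floor = 1e-4,
                    max_epochs = 300L, early_stop_patience = 300L,
                    val_fraction = 0.1, seed = 6)
  model <- dnn_train(X, y, cfg)
  acc <- mean(as.integer(dnn_predict(model, X) >= 0.5) == y)
  expect_equal(acc, 1.0)
})

test_that("training rejects degenerate inputs", {
  d <- shifted_matrix(30, 5, 2, 1)
  expect_error(dnn_train(d$X, rep(1, 60)), "both classes")
  bad <- d$X; bad[1, 1] <- NA
  expect_error(dnn_train(bad, d$y), "non-finite")
})
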