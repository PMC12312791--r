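test_that("the worked confusion table reproduces its closed-form metrics", {
  m <- classification_metrics(list(TP = 90, FN = 10, TN = 80, FP = 20))
  expect_equal(m$precision, 0.8182, tolerance = 1e-4)
  expect_equal(m$recall, 0.9000, tolerance = 1e-4)
  expect_equal(m$specificity, 0.8000, tolerance = 1e-4)
  expect_equal(m$accuracy, 0.8500, tolerance = 1e-4)
  expect_equal(m$npv, 0.8889, tolerance = 1e-4)
  expect_equal(m$f1, 0.8571, tolerance = 1e-4)
  expect_equal(m$mcc, 0.7035, tolerance = 1e-4)
  expect_equal(m$kappa, 0.7000, tolerance = 1e-4)
  expect_equal(m$dor, 36.0)
  expect_equal(m$dp, 1.9757, tolerance = 1e-4)
})

test_that("perfect and no-information classifiers hit the reference points", {
  perfect <- classification_metrics(list(TP = 50, FN = 0, TN = 50, FP = 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$kappa, 1)
  flat <- classification_metrics(list(TP = 25, FN = 25, TN = 25, FP = 25))
  expect_equal(flat$mcc, 0)
  expect_equal(flat$kappa, 0)
  expect_equal(flat$dor, 1)
  expect_equal(flat$dp, 0)
})

test_that("confusion counting applies the >= threshold tie rule", {
  cc <- confusion(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(cc[c("TP", "TN", "FP", "FN")], list(TP = 1L, TN = 1L, FP = 0L, FN = 0L),
               ignore_attr = TRUE)
  expect_equal(confusion(0.5, 0, 0.5)$FP, 1L)  # exactly-threshold is positive
  expect_equal(confusion(rep(0, 7), rep(1, 7), 0.5)$FN, 7L)
  expect_error(confusion(c(0.1, 0.2), 1), "length")
})

test_that("zero cells trigger the continuity correction for DOR/DP only", {
  m <- classification_metrics(list(TP = 10, FN = 0, TN = 8, FP = 2))
  expect_equal(m$dor, (10.5 * 8.5) / (2.5 * 0.5))
  expect_equal(m$recall, 1)  # uncorrected
  # 0/0 rates are undefined markers, not zeros
  none_called <- classification_metrics(list(TP = 0, FN = 5, TN = 5, FP = 0))
  expect_true(is.na(none_called$precision))
})

test_that("classification metrics agree with brute-force oracles", {
  set.seed(30)
  for (i in 1:200) {
    cc <- random_confusion()
    m <- classification_metrics(cc)
    v <- confusion_to_vectors(cc)
    expect_equal(m$mcc, mcc_brute(v$pred, v$truth), tolerance = 1e-12)
    expect_equal(m$kappa, kappa_brute(v$pred, v$truth), tolerance = 1e-12)
    expect_equal(m$accuracy, mean(v$pred == v$truth), tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with pairwise concordance counting", {
  expect_equal(ranking_metrics(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0))$auc, 1)
  expect_equal(ranking_metrics(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(ranking_metrics(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(31)
  for (i in 1:100) {
    n <- 40
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)  # coarse grid forces ties
    expect_equal(ranking_metrics(scores, labels)$auc,
                 auc_brute(scores, labels), tolerance = 1e-12)
  }
  expect_error(ranking_metrics(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(32)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.5)
  base <- ranking_metrics(scores, labels)$auc
  expect_equal(ranking_metrics(qlogis(scores), labels)$auc, base)
  expect_equal(ranking_metrics(scores^3, labels)$auc, base)
})

test_that("Bernoulli KL divergence matches its closed form", {
  labels <- rep(c(1, 0), 50)
  expect_equal(dkl(labels, rep(0.5, 100)), 0)
  expect_lt(abs(dkl(labels, rep(0.6, 100)) - 0.02041), 1e-5)
  # as the mean score collapses to zero with positives present, KL grows
  expect_gt(dkl(labels, rep(1e-9, 100)), 5)
})

test_that("lift concentrates where the ranking puts positives", {
  labels <- c(rep(1, 10), rep(0, 90))
  scores <- seq(1, 0.01, length.out = 100)  # all positives in the top decile
  lc <- lift_curve(scores, labels, 10)
  expect_equal(lc$lift[1], 10)
  expect_equal(lc$lift[-1], rep(0, 9))
  anti <- lift_curve(rev(scores), labels, 10)
  expect_equal(anti$lift[1], 0)
  set.seed(33)
  random <- lift_curve(runif(5000), rbinom(5000, 1, 0.3), 10)
  expect_true(all(abs(random$lift - 1) < 0.25))
  expect_error(lift_curve(runif(5), c(1, 0, 1, 0, 1), 10), "n_bins")
})

test_that("JM distance matches closed forms and respects its bounds", {
  set.seed(34)
  x <- as.numeric(scale(rnorm(200)))       # mean 0, var exactly 1
  expect_equal(jm_distance(cbind(x), cbind(x + 1)), 0.4848, tolerance = 1e-4)
  expect_equal(jm_distance(cbind(x), cbind(x)), 0)
  expect_equal(jm_distance(cbind(x), cbind(x + 1e4)), sqrt(2), tolerance = 1e-6)
  # monotone in mean separation at fixed variance
  gaps <- c(0, 0.5, 1, 2, 4)
  jm <- vapply(gaps, function(g) jm_distance(cbind(x), cbind(x + g)), numeric(1))
  expect_true(all(diff(jm) > 0))
  expect_true(all(jm >= 0 & jm <= sqrt(2)))
  expect_error(jm_distance(cbind(1), cbind(x)), ">= 2 samples")
})

test_that("per-block JM reports each feature category", {
  set.seed(35)
  X <- cbind(matrix(rnorm(400), 200, 2), matrix(rnorm(400), 200, 2))
  y <- rep(c(0, 1), each = 100)
  X[y == 1, 1:2] <- X[y == 1, 1:2] + 2   # only block A separates
  out <- jm_by_block(X, y, list(A = 1:2, B = 3:4))
  expect_gt(out["A"], 0.9)
  expect_lt(out["B"], 0.3)
})
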