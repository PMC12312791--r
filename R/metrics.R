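#' Confusion counts at a threshold
#'
#' A score greater than or equal to the threshold is a positive call
#' (documented tie rule: exactly-threshold scores count positive).
#'
#' @param scores Numeric scores in [0, 1].
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold (default 0.5).
#' @return List with `TP`, `FP`, `TN`, `FN`, `n`, `threshold`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  pred <- as.integer(scores >= threshold)
  list(TP = sum(pred == 1L & labels == 1), FP = sum(pred == 1L & labels == 0),
       TN = sum(pred == 0L & labels == 0), FN = sum(pred == 0L & labels == 1),
       n = length(labels), threshold = threshold)
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Threshold-based classification metrics
#'
#' Computes precision, recall, accuracy, specificity, NPV, F1, Matthews
#' correlation, Cohen's kappa, diagnostic odds ratio (DOR) and discriminant
#' power DP = (sqrt(3)/pi) * ln(DOR) from a confusion table. When any cell
#' is zero, DOR and DP use the Haldane-Anscombe continuity correction
#' (+0.5 on all four cells, those two metrics only). Rates with an empty
#' denominator are reported as `NA` (undefined), never silently as 0.
#'
#' @param c A [confusion()] result (or list with TP/FP/TN/FN).
#' @return Named list of metrics.
#' @export
classification_metrics <- function(c) {
  TP <- c$TP; FP <- c$FP; TN <- c$TN; FN <- c$FN
  n <- TP + FP + TN + FN
  if (n == 0) stopf("empty confusion table")
  precision <- safe_div(TP, TP + FP)
  recall <- safe_div(TP, TP + FN)
  specificity <- safe_div(TN, TN + FP)
  accuracy <- (TP + TN) / n
  npv <- safe_div(TN, TN + FN)
  f1 <- if (is.na(precision) || is.na(recall) || (precision + recall) == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den
  po <- accuracy
  pe <- ((TP + FP) * (TP + FN) + (TN + FN) * (TN + FP)) / n^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  cells <- c(TP, FP, TN, FN)
  if (any(cells == 0)) cells <- cells + 0.5
  dor <- (cells[1] * cells[3]) / (cells[2] * cells[4])
  dp <- (sqrt(3) / pi) * log(dor)
  list(precision = precision, recall = recall, specificity = specificity,
       accuracy = accuracy, npv = npv, f1 = f1, mcc = mcc, kappa = kappa,
       dor = dor, dp = dp, n = n)
}

#' Ranking metrics: AUC and AUPRC
#'
#' AUC uses the rank (Mann-Whitney) formulation, counting tied
#' positive/negative score pairs as one half. AUPRC is the step-interpolated
#' average precision over thresholds at the distinct score values. The ROC
#' and precision-recall curves are returned as data.frames.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return List with `auc`, `auprc`, `roc` (fpr/tpr), `prc`
#'   (recall/precision).
#' @export
ranking_metrics <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stopf("both classes required for ranking metrics")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # sweep thresholds at distinct scores, descending
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  y_sorted <- labels[ord]
  cum_tp <- cumsum(y_sorted)
  cum_fp <- cumsum(1 - y_sorted)
  last_of_group <- c(diff(s_sorted) != 0, TRUE)
  tp <- cum_tp[last_of_group]
  fp <- cum_fp[last_of_group]
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  prec <- tp / (tp + fp)
  rec <- tpr
  auprc <- sum(diff(c(0, rec)) * prec)
  list(auc = auc, auprc = auprc,
       roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)),
       prc = data.frame(recall = rec, precision = prec))
}

#' Bernoulli Kullback-Leibler divergence of prevalence vs mean score
#'
#' `KL(Bernoulli(p) || Bernoulli(q))` in natural log units, where `p` is the
#' observed label prevalence and `q` the mean predicted score (clipped to
#' [1e-12, 1 - 1e-12]). A convention choice: it measures how far the
#' model's average predicted positive rate sits from the true positive
#' rate; 0 means the two Bernoulli distributions coincide.
#'
#' @param labels Binary labels (0/1).
#' @param scores Numeric scores in [0, 1].
#' @return Divergence in nats.
#' @export
dkl <- function(labels, scores) {
  if (length(labels) < 1L) stopf("need at least one sample")
  p <- mean(labels)
  q <- min(max(mean(scores), 1e-12), 1 - 1e-12)
  term <- function(a, b) if (a == 0) 0 else a * log(a / b)
  term(p, q) + term(1 - p, 1 - q)
}

#' Lift curve
#'
#' Samples are sorted by decreasing score (stable, so ties keep input
#' order) and split into `n_bins` contiguous bins of near-equal size; the
#' lift of a bin is the positive rate within the bin divided by the overall
#' prevalence. A useless ranker has lift about 1 everywhere; a perfect one
#' concentrates positives in the top bins.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), both classes present.
#' @param n_bins Number of bins (default 10: deciles).
#' @return Data.frame with `bin`, `n`, `positives`, `precision`, `lift`.
#' @export
lift_curve <- function(scores, labels, n_bins = 10L) {
  n <- length(scores)
  if (n_bins > n) stopf("n_bins exceeds the number of samples")
  prevalence <- mean(labels)
  if (prevalence == 0 || prevalence == 1) stopf("both classes required for lift")
  ord <- order(-scores)   # stable: ties broken by input order
  y <- labels[ord]
  bin <- rep(seq_len(n_bins), times = diff(floor(seq(0, n, length.out = n_bins + 1))))
  pos <- tapply(y, bin, sum)
  size <- tapply(y, bin, length)
  prec <- as.numeric(pos / size)
  data.frame(bin = seq_len(n_bins), n = as.integer(size),
             positives = as.integer(pos), precision = prec,
             lift = prec / prevalence)
}

#' Jeffries-Matusita distance between two classes
#'
#' Each class is modelled as a diagonal-covariance Gaussian (per-feature
#' variances floored at `var_floor`). The Bhattacharyya distance is
#' `B = (1/8) (mu1 - mu0)' S^-1 (mu1 - mu0) + (1/2) ln(det S / sqrt(det S0
#' det S1))` with `S = (S0 + S1)/2`, and `JM = sqrt(2 (1 - exp(-B)))`,
#' bounded in [0, sqrt(2)]: 0 for identical class distributions, the upper
#' bound for perfectly separable ones.
#'
#' @param X_class0,X_class1 Numeric matrices (rows = samples of each class).
#' @param var_floor Lower bound on per-feature variances.
#' @return The JM distance (scalar).
#' @export
jm_distance <- function(X_class0, X_class1, var_floor = 1e-6) {
  X0 <- as.matrix(X_class0)
  X1 <- as.matrix(X_class1)
  if (nrow(X0) < 2L || nrow(X1) < 2L) stopf("need >= 2 samples per class")
  if (ncol(X0) != ncol(X1)) stopf("class matrices differ in dimension")
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  v0 <- pmax(apply(X0, 2, stats::var), var_floor)
  v1 <- pmax(apply(X1, 2, stats::var), var_floor)
  vbar <- (v0 + v1) / 2
  B <- sum((mu1 - mu0)^2 / vbar) / 8 +
    0.5 * (sum(log(vbar)) - 0.5 * (sum(log(v0)) + sum(log(v1))))
  sqrt(2 * (1 - exp(-B)))
}

#' Per-block JM separability report
#'
#' Computes [jm_distance()] restricted to named column blocks of a feature
#' matrix, e.g. the embedding block and each GO sub-ontology block.
#'
#' @param X Feature matrix.
#' @param y Binary labels (0/1).
#' @param blocks Named list of column-index vectors.
#' @return Named numeric vector of JM distances.
#' @export
jm_by_block <- function(X, y, blocks) {
  vapply(blocks, function(cols) {
    jm_distance(X[y == 0, cols, drop = FALSE], X[y == 1, cols, drop = FALSE])
  }, numeric(1))
}
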