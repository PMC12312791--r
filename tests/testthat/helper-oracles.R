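# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the package implementations they check.

# AUC as the fraction of positive/negative score pairs ranked concordantly,
# ties counted one half.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Cohen's kappa from observed and chance agreement computed off the raw
# prediction vectors (not the closed-form marginal shortcut).
kappa_brute <- function(pred, truth) {
  po <- mean(pred == truth)
  pe <- mean(pred == 1) * mean(truth == 1) + mean(pred == 0) * mean(truth == 0)
  (po - pe) / (1 - pe)
}

# MCC as the Pearson correlation of the binary prediction and truth vectors.
mcc_brute <- function(pred, truth) {
  suppressWarnings(stats::cor(pred, truth))
}

# Random confusion counts with all cells positive.
random_confusion <- function() {
  as.list(stats::setNames(sample(1:60, 4, replace = TRUE),
                          c("TP", "FP", "TN", "FN")))
}

# Expand a confusion table back into prediction/truth vectors.
confusion_to_vectors <- function(cc) {
  pred <- c(rep(1, cc$TP), rep(1, cc$FP), rep(0, cc$TN), rep(0, cc$FN))
  truth <- c(rep(1, cc$TP), rep(0, cc$FP), rep(0, cc$TN), rep(1, cc$FN))
  list(pred = pred, truth = truth)
}
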