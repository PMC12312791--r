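#' SVM-weight feature selection
#'
#' Ranks features by the absolute weights of a linear maximum-margin
#' classifier (soft-margin SVM, C = 1 by default) fitted on standardized
#' training data, and keeps the top `min(k, p)`. Standardization parameters
#' are fitted on the training matrix and stored in the mask so that exactly
#' the same transform is applied at prediction time; zero-variance features
#' get scale 1 (their standardized column is constant zero, so they rank
#' last). Ties in |weight| are broken by lower column index. The mask is
#' fitted on training folds only -- the interface never sees held-out data.
#'
#' @param X_train Numeric matrix `n x p` (training fold only).
#' @param y_train Binary labels (0/1), both classes present.
#' @param k Number of features to keep (default 4000).
#' @param cost Soft-margin cost C of the linear SVM.
#' @return An object of class `selection_mask`: `kept_indices` (sorted
#'   ascending), `k`, `center`, `scale`, `p`, `weights`.
#' @export
fit_selector <- function(X_train, y_train, k = 4000L, cost = 1) {
  X_train <- as.matrix(X_train)
  y_train <- as.integer(y_train)
  if (k < 1L) stopf("k must be >= 1")
  if (length(unique(y_train)) < 2L) stopf("y_train must contain both classes")
  if (nrow(X_train) < 2L) stopf("need at least 2 training samples")
  p <- ncol(X_train)
  center <- colMeans(X_train)
  scale <- apply(X_train, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- sweep(sweep(X_train, 2, center), 2, scale, "/")
  fit <- e1071::svm(x = Xs, y = factor(y_train, levels = c(0L, 1L)),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  ord <- order(-abs(w), seq_along(w))
  kept <- sort(ord[seq_len(min(k, p))])
  structure(
    list(kept_indices = kept, k = length(kept), center = center,
         scale = scale, p = p, weights = as.numeric(w)),
    class = "selection_mask"
  )
}

#' Apply a selection mask
#'
#' Standardizes `X` with the mask's stored training-fold parameters, then
#' keeps the selected columns. Labels are never consulted.
#'
#' @param X Numeric matrix `m x p` with the mask's source dimension.
#' @param mask A [fit_selector()] result.
#' @return Numeric matrix `m x k`.
#' @export
apply_mask <- function(X, mask) {
  X <- as.matrix(X)
  if (ncol(X) != mask$p) {
    stopf("feature dimension mismatch: mask expects %d columns, got %d",
          mask$p, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, mask$center), 2, mask$scale, "/")
  Xs[, mask$kept_indices, drop = FALSE]
}

#' Serialize / restore a selection mask as JSON
#'
#' @param mask A `selection_mask`.
#' @param path JSON path.
#' @return `path` invisibly; `read_selection_mask` returns the mask.
#' @export
write_selection_mask <- function(mask, path) {
  jsonlite::write_json(unclass(mask), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection_mask
#' @export
read_selection_mask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$kept_indices <- as.integer(obj$kept_indices)
  obj$k <- as.integer(obj$k)
  obj$p <- as.integer(obj$p)
  structure(obj, class = "selection_mask")
}
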