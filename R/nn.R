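#' Neural-head configuration
#'
#' The druggability classifier is a small fully connected network: three
#' hidden layers of 128, 64 and 32 ReLU units, batch normalization after
#' each dense layer, dropout 0.5 after hidden layers 1 and 2, an L2 penalty
#' of 0.01 on the dense weights, and a sigmoid output unit producing a score
#' in [0, 1]. It is trained with the Adam optimizer on binary cross-entropy,
#' batch size 32, with a learning rate starting at 2e-4 and halving every 5
#' epochs down to a floor of 2.5e-5, and early stopping (patience 5) on the
#' loss of a stratified 10% validation split of the training data, restoring
#' the best weights.
#'
#' @param hidden_units Integer vector of hidden layer sizes.
#' @param dropout_rate Drop probability after hidden layers 1 and 2.
#' @param l2_penalty L2 coefficient on dense kernel weights.
#' @param lr_initial,lr_halving_every,lr_floor Learning-rate schedule.
#' @param batch_size Minibatch size.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param max_epochs Hard epoch cap (early stopping usually ends first).
#' @param val_fraction Fraction of the training data held out (stratified)
#'   for early-stopping monitoring.
#' @param bn_momentum Momentum of the batch-norm running statistics.
#' @param seed Seed controlling initialization, the validation split,
#'   shuffling and dropout.
#' @return An object of class `dnn_config`.
#' @export
dnn_config <- function(hidden_units = c(128L, 64L, 32L), dropout_rate = 0.5,
                       l2_penalty = 0.01, lr_initial = 2e-4,
                       lr_halving_every = 5L, lr_floor = 2.5e-5,
                       batch_size = 32L, early_stop_patience = 5L,
                       max_epochs = 100L, val_fraction = 0.1,
                       bn_momentum = 0.9, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  if (any(hidden_units < 1L)) stopf("hidden_units must be positive")
  if (lr_initial <= 0 || lr_floor <= 0) stopf("learning rates must be positive")
  if (val_fraction <= 0 || val_fraction >= 1) stopf("val_fraction must be in (0, 1)")
  structure(
    list(hidden_units = as.integer(hidden_units), dropout_rate = dropout_rate,
         l2_penalty = l2_penalty, lr_initial = lr_initial,
         lr_halving_every = as.integer(lr_halving_every), lr_floor = lr_floor,
         batch_size = as.integer(batch_size),
         early_stop_patience = as.integer(early_stop_patience),
         max_epochs = as.integer(max_epochs), val_fraction = val_fraction,
         bn_momentum = bn_momentum, seed = as.integer(seed)),
    class = "dnn_config"
  )
}

#' Step-halving learning-rate schedule
#'
#' `lr(e) = max(lr_floor, lr_initial / 2^floor(e / lr_halving_every))` for
#' 0-based epoch `e`: 2e-4 at epoch 0, halving every 5 epochs, clamped at
#' 2.5e-5 (reached after 15 epochs with the defaults).
#'
#' @param epoch 0-based epoch index.
#' @param config A [dnn_config()].
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config = dnn_config()) {
  if (any(epoch < 0)) stopf("epoch must be >= 0")
  pmax(config$lr_floor,
       config$lr_initial / 2^floor(epoch / config$lr_halving_every))
}

#' Closed-form trainable-parameter count of the neural head
#'
#' Dense kernels and biases plus the batch-norm scale/shift pairs of each
#' hidden layer, plus the sigmoid output unit (running statistics are not
#' trainable).
#'
#' @param input_dim Number of input features k.
#' @param hidden_units Hidden layer sizes.
#' @return Integer parameter count.
#' @export
n_dnn_parameters <- function(input_dim, hidden_units = c(128L, 64L, 32L)) {
  dims <- c(input_dim, hidden_units)
  total <- 0L
  for (l in seq_along(hidden_units)) {
    total <- total + dims[l] * dims[l + 1L] + dims[l + 1L] + 2L * dims[l + 1L]
  }
  total + hidden_units[length(hidden_units)] + 1L
}

BN_EPS <- 1e-5

init_params <- function(input_dim, hidden_units) {
  dims <- c(input_dim, hidden_units)
  layers <- lapply(seq_along(hidden_units), function(l) {
    fan_in <- dims[l]
    out <- dims[l + 1L]
    list(
      W = matrix(stats::rnorm(fan_in * out, sd = sqrt(2 / fan_in)), fan_in, out),
      b = rep(0, out), gamma = rep(1, out), beta = rep(0, out),
      rmean = rep(0, out), rvar = rep(1, out)
    )
  })
  last <- hidden_units[length(hidden_units)]
  out_layer <- list(W = matrix(stats::rnorm(last, sd = sqrt(1 / last)), last, 1L),
                    b = 0)
  list(hidden = layers, out = out_layer)
}

# Inference-mode forward pass: running BN statistics, no dropout.
forward_infer <- function(params, X) {
  A <- X
  for (layer in params$hidden) {
    Z <- sweep(A %*% layer$W, 2, layer$b, "+")
    inv <- 1 / sqrt(layer$rvar + BN_EPS)
    xhat <- sweep(sweep(Z, 2, layer$rmean), 2, inv, "*")
    A <- pmax(sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+"), 0)
  }
  z <- drop(A %*% params$out$W) + params$out$b
  1 / (1 + exp(-z))
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

l2_term <- function(params, l2) {
  if (l2 == 0) return(0)
  l2 * (sum(vapply(params$hidden, function(l) sum(l$W^2), numeric(1))) +
          sum(params$out$W^2))
}

# One training forward+backward pass; returns gradients in the same shape
# as the trainable parameters, plus updated running statistics.
train_step_grads <- function(params, Xb, yb, config) {
  nb <- nrow(Xb)
  nh <- length(params$hidden)
  cache <- vector("list", nh)
  A <- Xb
  for (l in seq_len(nh)) {
    layer <- params$hidden[[l]]
    Z <- sweep(A %*% layer$W, 2, layer$b, "+")
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(sweep(Z, 2, mu), 2, inv, "*")
    Abn <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
    H <- pmax(Abn, 0)
    mask <- NULL
    if (l <= 2L && config$dropout_rate > 0) {
      mask <- matrix(stats::runif(length(H)) >= config$dropout_rate,
                     nrow(H), ncol(H)) / (1 - config$dropout_rate)
      H <- H * mask
    }
    cache[[l]] <- list(A_prev = A, xhat = xhat, inv = inv, Abn = Abn,
                       mask = mask, mu = mu, v = v)
    A <- H
  }
  z <- drop(A %*% params$out$W) + params$out$b
  p <- 1 / (1 + exp(-z))

  grads <- list(hidden = vector("list", nh), out = NULL)
  dz <- matrix((p - yb) / nb, ncol = 1L)
  grads$out <- list(W = crossprod(A, dz) + 2 * config$l2_penalty * params$out$W,
                    b = sum(dz))
  dH <- dz %*% t(params$out$W)
  for (l in rev(seq_len(nh))) {
    layer <- params$hidden[[l]]
    cc <- cache[[l]]
    if (!is.null(cc$mask)) dH <- dH * cc$mask
    dAbn <- dH * (cc$Abn > 0)
    dgamma <- colSums(dAbn * cc$xhat)
    dbeta <- colSums(dAbn)
    dxhat <- sweep(dAbn, 2, layer$gamma, "*")
    mean_dxhat <- colMeans(dxhat)
    mean_dxhat_xhat <- colMeans(dxhat * cc$xhat)
    dZ <- sweep(dxhat, 2, mean_dxhat) - sweep(cc$xhat, 2, mean_dxhat_xhat, "*")
    dZ <- sweep(dZ, 2, cc$inv, "*")
    grads$hidden[[l]] <- list(
      W = crossprod(cc$A_prev, dZ) + 2 * config$l2_penalty * layer$W,
      b = colSums(dZ), gamma = dgamma, beta = dbeta,
      mu = cc$mu, v = cc$v
    )
    if (l > 1L) dH <- dZ %*% t(layer$W)
  }
  list(grads = grads, loss = bce_loss(p, yb))
}

adam_update <- function(value, grad, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(value = value - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train the druggability neural head
#'
#' Fits the network described in [dnn_config()] on a feature matrix (one row
#' per protein, typically the output of [apply_mask()]) and binary labels.
#' Fully seeded: identical data, config and seed reproduce identical
#' weights. Early stopping restores the weights of the best validation
#' epoch.
#'
#' @param X Numeric matrix `n x k`.
#' @param y Binary labels (0/1), both classes present.
#' @param config A [dnn_config()].
#' @return An object of class `druggability_dnn` with `params`, `config`,
#'   `history` (per-epoch data.frame), `best_epoch`, `input_dim`.
#' @export
dnn_train <- function(X, y, config = dnn_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(is.finite(X))) stopf("non-finite value in training matrix")
  if (length(unique(y)) < 2L) stopf("training labels must contain both classes")
  if (nrow(X) != length(y)) stopf("X and y sizes differ")

  with_local_seed(config$seed, {
    # stratified validation split for early-stopping monitoring
    val_idx <- unlist(lapply(split(seq_along(y), y), function(idx) {
      n_val <- max(1L, round(config$val_fraction * length(idx)))
      if (n_val >= length(idx)) stopf("too few samples for the validation split")
      sample(idx, n_val)
    }), use.names = FALSE)
    tr_idx <- setdiff(seq_along(y), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
    if (length(unique(ytr)) < 2L) stopf("both classes required in the training part")

    params <- init_params(ncol(X), config$hidden_units)
    new_state <- function(v) list(m = v * 0, v = v * 0)
    opt <- list(
      hidden = lapply(params$hidden, function(l)
        list(W = new_state(l$W), b = new_state(l$b),
             gamma = new_state(l$gamma), beta = new_state(l$beta))),
      out = list(W = new_state(params$out$W), b = new_state(params$out$b))
    )

    history <- data.frame(epoch = integer(0), lr = numeric(0),
                          train_loss = numeric(0), val_loss = numeric(0))
    best_val <- Inf; best_params <- params; best_epoch <- -1L
    wait <- 0L; t_step <- 0L
    n_tr <- nrow(Xtr)

    for (epoch in seq_len(config$max_epochs) - 1L) {
      lr <- lr_schedule(epoch, config)
      perm <- sample.int(n_tr)
      batch_starts <- seq(1L, n_tr, by = config$batch_size)
      epoch_losses <- numeric(length(batch_starts))
      for (bi in seq_along(batch_starts)) {
        idx <- perm[batch_starts[bi]:min(batch_starts[bi] + config$batch_size - 1L, n_tr)]
        step <- train_step_grads(params, Xtr[idx, , drop = FALSE], ytr[idx], config)
        t_step <- t_step + 1L
        for (l in seq_along(params$hidden)) {
          for (nm in c("W", "b", "gamma", "beta")) {
            upd <- adam_update(params$hidden[[l]][[nm]], step$grads$hidden[[l]][[nm]],
                               opt$hidden[[l]][[nm]], lr, t_step)
            params$hidden[[l]][[nm]] <- upd$value
            opt$hidden[[l]][[nm]] <- upd$state
          }
          m <- config$bn_momentum
          params$hidden[[l]]$rmean <- m * params$hidden[[l]]$rmean +
            (1 - m) * step$grads$hidden[[l]]$mu
          params$hidden[[l]]$rvar <- m * params$hidden[[l]]$rvar +
            (1 - m) * step$grads$hidden[[l]]$v
        }
        for (nm in c("W", "b")) {
          upd <- adam_update(params$out[[nm]], step$grads$out[[nm]],
                             opt$out[[nm]], lr, t_step)
          params$out[[nm]] <- upd$value
          opt$out[[nm]] <- upd$state
        }
        epoch_losses[bi] <- step$loss
      }
      train_loss <- mean(epoch_losses) + l2_term(params, config$l2_penalty)
      val_loss <- bce_loss(forward_infer(params, Xval), yval) +
        l2_term(params, config$l2_penalty)
      if (!is.finite(val_loss) || !is.finite(train_loss)) {
        stopf("non-finite loss at epoch %d", epoch)
      }
      history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                           train_loss = train_loss,
                                           val_loss = val_loss))
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) break
      }
    }

    structure(
      list(params = best_params, config = config, history = history,
           best_epoch = best_epoch, input_dim = ncol(X)),
      class = "druggability_dnn"
    )
  })
}

#' Score proteins with a trained neural head
#'
#' Inference mode: dropout disabled, batch normalization uses running
#' statistics, so scores are batch-size independent. Output is in [0, 1].
#'
#' @param model A [dnn_train()] result.
#' @param X Numeric matrix `m x k` with `k = model$input_dim`.
#' @return Numeric score vector of length `m`.
#' @export
dnn_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    stopf("input has %d columns but the model expects %d", ncol(X), model$input_dim)
  }
  as.numeric(forward_infer(model$params, X))
}
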