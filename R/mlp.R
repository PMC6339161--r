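#' Network architecture and training specification
#'
#' The regressor is a feedforward network with 3 hidden layers of 100
#' rectifier units and dropout 0.5, optionally initialized by layer-wise
#' autoencoder pretraining, fine-tuned with Adam on mean squared error with
#' early stopping on an inner 10% validation split. All fields can be
#' overridden, but the architecture defaults are the study configuration.
#'
#' @param hidden_layers number of hidden layers (default 3)
#' @param units units per hidden layer (default 100)
#' @param dropout dropout probability on hidden activations (default 0.5)
#' @param pretrain layer-wise autoencoder pretraining (default `TRUE`)
#' @param epochs fine-tuning epochs (default 300)
#' @param pretrain_epochs autoencoder epochs per layer (default 30)
#' @param learning_rate Adam step size (default 1e-3)
#' @param batch_size minibatch size (default 32)
#' @param patience early-stopping patience in epochs (default 25)
#' @param val_fraction inner validation fraction (default 0.1)
#' @param seed integer seed for weight init, dropout and batch order
#' @return an object of class `network_spec`
#' @export
network_spec <- function(hidden_layers = 3L, units = 100L, dropout = 0.5,
                         pretrain = TRUE, epochs = 300L, pretrain_epochs = 30L,
                         learning_rate = 1e-3, batch_size = 32L,
                         patience = 25L, val_fraction = 0.1, seed = 1L) {
  structure(list(hidden_layers = as.integer(hidden_layers),
                 units = as.integer(units), dropout = dropout,
                 pretrain = isTRUE(pretrain), epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 patience = as.integer(patience), val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "network_spec")
}

relu <- function(z) z * (z > 0)

init_layer <- function(n_in, n_out) {
  # He initialization for rectifier units
  list(W = matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

adam_state <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params)) {
    st <- state[[l]]
    st$mW <- beta1 * st$mW + (1 - beta1) * grads[[l]]$W
    st$vW <- beta2 * st$vW + (1 - beta2) * grads[[l]]$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * grads[[l]]$b
    st$vb <- beta2 * st$vb + (1 - beta2) * grads[[l]]$b^2
    mW <- st$mW / (1 - beta1^t); vW <- st$vW / (1 - beta2^t)
    mb <- st$mb / (1 - beta1^t); vb <- st$vb / (1 - beta2^t)
    params[[l]]$W <- params[[l]]$W - lr * mW / (sqrt(vW) + eps)
    params[[l]]$b <- params[[l]]$b - lr * mb / (sqrt(vb) + eps)
    state[[l]] <- st
  }
  list(params = params, state = state)
}

# forward pass; returns activations of every layer (pre-output linear)
mlp_forward <- function(params, X, dropout = 0, train = FALSE) {
  L <- length(params)
  A <- X
  acts <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% params[[l]]$W, 2, params[[l]]$b, "+")
    if (l < L) {
      A <- relu(Z)
      if (train && dropout > 0) {
        keep <- 1 - dropout
        mask <- matrix(rbinom(length(A), 1, keep), nrow(A)) / keep
        A <- A * mask
      }
    } else {
      A <- Z
    }
    acts[[l]] <- A
  }
  acts
}

# backprop for MSE loss; returns gradient list matching params
mlp_backprop <- function(params, X, y, dropout) {
  L <- length(params)
  n <- nrow(X)
  A <- X
  As <- vector("list", L + 1)
  As[[1]] <- X
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- sweep(As[[l]] %*% params[[l]]$W, 2, params[[l]]$b, "+")
    if (l < L) {
      A <- relu(Z)
      if (dropout > 0) {
        keep <- 1 - dropout
        mask <- matrix(rbinom(length(A), 1, keep), nrow(A)) / keep
        A <- A * mask
        masks[[l]] <- mask
      }
    } else {
      A <- Z
    }
    As[[l + 1]] <- A
  }
  pred <- As[[L + 1]]
  delta <- 2 * (pred - y) / n          # d(MSE)/d(pred)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(As[[l]], delta), b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(params[[l]]$W)
      if (!is.null(masks[[l - 1]])) delta <- delta * masks[[l - 1]]
      delta <- delta * (As[[l]] > 0)
    }
  }
  list(grads = grads, loss = mean((pred - y)^2))
}

#' Layer-wise autoencoder pretraining
#'
#' Trains one autoencoder per hidden layer: the layer's weights are fitted to
#' reconstruct their own input (rectifier encoder, linear decoder, MSE), then
#' the encoded activations feed the next layer. The resulting encoder weights
#' initialize the regressor's hidden stack.
#'
#' @param X standardized numeric feature matrix (no missing values; constant
#'   columns are dropped with a warning)
#' @param spec a [network_spec()]
#' @return list with `params` (one `W`/`b` pair per hidden layer), `losses`
#'   (reconstruction-loss history per layer) and `kept` (column indices kept)
#' @export
pretrain_autoencoder <- function(X, spec = network_spec()) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("X contains missing values", call. = FALSE)
  keep <- which(apply(X, 2, function(v) sd(v) > 0))
  if (length(keep) < ncol(X)) {
    warning(sprintf("dropping %d constant column(s) before pretraining",
                    ncol(X) - length(keep)), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  with_seed(derive_seed(spec$seed, 701L), {
    A <- X
    params <- vector("list", spec$hidden_layers)
    losses <- vector("list", spec$hidden_layers)
    for (l in seq_len(spec$hidden_layers)) {
      enc <- init_layer(ncol(A), spec$units)
      dec <- init_layer(spec$units, ncol(A))
      ae <- list(enc, dec)
      st <- adam_state(ae)
      hist <- numeric(spec$pretrain_epochs)
      t <- 0
      for (ep in seq_len(spec$pretrain_epochs)) {
        idx <- sample(nrow(A))
        batches <- split(idx, ceiling(seq_along(idx) / spec$batch_size))
        ep_loss <- 0
        for (b in batches) {
          t <- t + 1
          bp <- mlp_backprop(ae, A[b, , drop = FALSE], A[b, , drop = FALSE],
                             dropout = 0)
          upd <- adam_update(ae, bp$grads, st, spec$learning_rate, t)
          ae <- upd$params
          st <- upd$state
          ep_loss <- ep_loss + bp$loss * length(b)
        }
        hist[ep] <- ep_loss / nrow(A)
      }
      params[[l]] <- ae[[1]]
      losses[[l]] <- hist
      A <- relu(sweep(A %*% ae[[1]]$W, 2, ae[[1]]$b, "+"))
    }
    list(params = params, losses = losses, kept = keep)
  })
}

#' Train the feedforward regressor
#'
#' Applies a variance-stabilizing signed log transform
#' (`sign(x) log(1 + |x|)`, appropriate for the heavily right-skewed spectral
#' power features; disable with `input_transform = "none"`), z-scores on the
#' training data, optionally initializes the hidden stack by
#' [pretrain_autoencoder()], and fine-tunes the full network on the target
#' with Adam, minibatches, dropout on hidden layers and early stopping on an
#' inner validation split. Predictions are clipped to `bounds` at inference.
#' Training is deterministic given `spec$seed`.
#'
#' @param X numeric feature matrix (rows = sessions); missing values are not
#'   allowed
#' @param y numeric target on its native scale
#' @param spec a [network_spec()]
#' @param bounds optional length-2 prediction clip range (e.g. `c(-3, 3)`)
#' @param input_transform `"signed_log"` (default) or `"none"`
#' @return an object of class `mlp_model`
#' @export
train_regressor <- function(X, y, spec = network_spec(), bounds = NULL,
                            input_transform = c("signed_log", "none")) {
  input_transform <- match.arg(input_transform)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y dimensions differ", call. = FALSE)
  if (nrow(X) < 8L) stop("too few rows to form a training batch", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X))) stop("X contains missing values", call. = FALSE)
  if (input_transform == "signed_log") X <- sign(X) * log1p(abs(X))
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  keep <- which(scale_ > 0)
  if (!length(keep)) stop("all features are constant", call. = FALSE)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, center[keep]), 2, scale_[keep], "/")
  # target standardized for optimization; predictions mapped back
  y_center <- mean(y)
  y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 0
  ys <- if (y_scale > 0) (y - y_center) / y_scale else rep(0, length(y))
  pre <- NULL
  if (spec$pretrain) {
    pre <- suppressWarnings(pretrain_autoencoder(Xs, spec))
  }
  with_seed(derive_seed(spec$seed, 702L), {
    L <- spec$hidden_layers + 1L
    params <- vector("list", L)
    dims <- c(ncol(Xs), rep(spec$units, spec$hidden_layers), 1L)
    for (l in seq_len(L)) params[[l]] <- init_layer(dims[l], dims[l + 1])
    if (!is.null(pre)) for (l in seq_len(spec$hidden_layers)) params[[l]] <- pre$params[[l]]
    # inner validation split for early stopping
    n <- nrow(Xs)
    n_val <- floor(n * spec$val_fraction)
    use_es <- n_val >= 4L
    idx_all <- sample(n)
    val_idx <- if (use_es) idx_all[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(idx_all, val_idx)
    ytr <- matrix(ys[tr_idx], ncol = 1)
    Xtr <- Xs[tr_idx, , drop = FALSE]
    st <- adam_state(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    t <- 0
    train_hist <- numeric(spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      idx <- sample(nrow(Xtr))
      batches <- split(idx, ceiling(seq_along(idx) / spec$batch_size))
      ep_loss <- 0
      for (b in batches) {
        t <- t + 1
        bp <- mlp_backprop(params, Xtr[b, , drop = FALSE],
                           ytr[b, , drop = FALSE], spec$dropout)
        upd <- adam_update(params, bp$grads, st, spec$learning_rate, t)
        params <- upd$params
        st <- upd$state
        ep_loss <- ep_loss + bp$loss * length(b)
      }
      train_hist[ep] <- ep_loss / nrow(Xtr)
      if (use_es) {
        pv <- mlp_forward(params, Xs[val_idx, , drop = FALSE])[[L]]
        vl <- mean((pv - ys[val_idx])^2)
        if (vl < best$loss - 1e-9) {
          best <- list(loss = vl, params = params, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= spec$patience) break
        }
      } else {
        best <- list(loss = train_hist[ep], params = params, epoch = ep)
      }
    }
    structure(list(params = best$params, spec = spec, bounds = bounds,
                   input_transform = input_transform,
                   y_center = y_center, y_scale = y_scale,
                   center = center[keep], scale = scale_[keep],
                   features = colnames(X)[keep], kept = keep,
                   train_loss = train_hist[train_hist > 0],
                   val_loss = best$loss, best_epoch = best$epoch,
                   pretrain_losses = if (!is.null(pre)) pre$losses else NULL),
              class = "mlp_model")
  })
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d inputs -> %s -> 1 (dropout %.2f%s), best epoch %d\n",
              length(x$features),
              paste(rep(x$spec$units, x$spec$hidden_layers), collapse = "-"),
              x$spec$dropout,
              if (x$spec$pretrain) ", pretrained" else "",
              x$best_epoch))
  invisible(x)
}

#' Predict from a trained regressor
#'
#' @param object an `mlp_model`
#' @param newdata numeric matrix with the training feature columns
#' @param ... unused
#' @return numeric predictions, clipped to the model's bounds if set
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$features)) {
    miss <- setdiff(object$features, colnames(newdata))
    if (length(miss)) stop("newdata lacks feature(s): ",
                           paste(head(miss, 5), collapse = ", "), call. = FALSE)
    newdata <- newdata[, object$features, drop = FALSE]
  } else {
    newdata <- newdata[, object$kept, drop = FALSE]
  }
  if (identical(object$input_transform, "signed_log")) {
    newdata <- sign(newdata) * log1p(abs(newdata))
  }
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  p <- mlp_forward(object$params, Xs)[[length(object$params)]][, 1]
  p <- object$y_center + (if (object$y_scale > 0) object$y_scale else 0) * p
  if (!is.null(object$bounds)) p <- clamp(p, object$bounds[1], object$bounds[2])
  p
}

#' Weight-based variable importance (Garson decomposition)
#'
#' Garson's connection-weight effect size: within every layer each unit's
#' incoming absolute weights are normalized to shares, the shares are chained
#' from the inputs through all hidden layers to the output, and the resulting
#' per-input contributions are normalized to sum to one. Variables with high
#' effect size dominate the trained network's input-output mapping.
#'
#' @param model a trained [train_regressor()] model
#' @param feature_names optional names (default: the model's features)
#' @return data.frame of class `importance_table` with `feature` and
#'   `effect_size`, sorted decreasing
#' @export
variable_importance <- function(model, feature_names = NULL) {
  if (!inherits(model, "mlp_model")) stop("`model` must be a trained mlp_model",
                                          call. = FALSE)
  M <- NULL
  for (l in seq_along(model$params)) {
    W <- abs(model$params[[l]]$W)
    W <- sweep(W, 2, pmax(colSums(W), 1e-12), "/")  # per-unit input shares
    M <- if (is.null(M)) W else M %*% W
  }
  eff <- as.numeric(M)
  eff <- eff / sum(eff)
  nm <- feature_names %||% model$features %||% paste0("x", seq_along(eff))
  out <- data.frame(feature = nm, effect_size = eff, stringsAsFactors = FALSE)
  out <- out[order(-out$effect_size), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}
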