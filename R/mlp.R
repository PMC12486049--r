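# Small fully-connected regression network, written in plain matrix code:
# hidden blocks of linear -> ReLU -> batch normalization with widths halving
# from `n` down to 8, a single linear output unit, Adam with L2 weight
# decay, mini-batches, and early stopping with best-weights restore.

#' Training configuration for the fusion estimator
#'
#' @param n First hidden width; must be 8 times a power of two so the
#'   halving schedule terminates at 8.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty on the linear weights.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); best weights are restored.
#' @param bn_after_activation Place batch normalization after the ReLU
#'   (the default) or before it.
#' @param init_sd Normal-init standard deviation for weights; `NULL` uses
#'   `sqrt(2 / fan_in)` per layer. Biases start at zero.
#' @param seed RNG seed (weight init and batch shuffling).
#' @return A `tfo_train_config`.
#' @export
train_config <- function(n = 64, lr = 1e-3, weight_decay = 1e-4,
                         batch_size = 32, max_epochs = 300, patience = 25,
                         bn_after_activation = TRUE, init_sd = NULL,
                         seed = 1) {
  k <- n / 8
  if (n < 8 || k != 2^round(log2(k))) {
    abort("`n` must be 8 * 2^j so halving reaches 8.", class = "tfo_error_config")
  }
  structure(list(n = n, lr = lr, weight_decay = weight_decay,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience,
                 bn_after_activation = bn_after_activation,
                 init_sd = init_sd, seed = seed),
            class = "tfo_train_config")
}

#' Build an untrained fusion network
#'
#' Layer widths are `input_width, n, n/2, ..., 8, 1`; every hidden block is
#' linear -> ReLU -> batch normalization and the output is a single linear
#' unit.
#'
#' @param cfg A [train_config()].
#' @param input_width Number of input features (10 EPRs or 5 RoRs).
#' @return A `tfo_mlp` with initialized parameters.
#' @export
build_model <- function(cfg, input_width) {
  stopifnot(inherits(cfg, "tfo_train_config"), input_width >= 1)
  widths <- c(input_width, cfg$n / 2^(0:log2(cfg$n / 8)), 1)
  set.seed(cfg$seed)
  nh <- length(widths) - 2  # hidden blocks
  layers <- vector("list", nh + 1)
  for (l in seq_len(nh + 1)) {
    fin <- widths[l]; fout <- widths[l + 1]
    sd0 <- cfg$init_sd %||% sqrt(2 / fin)
    layers[[l]] <- list(
      W = matrix(rnorm(fin * fout, 0, sd0), fin, fout),
      b = rep(0, fout))
    if (l <= nh) {
      layers[[l]]$gamma <- rep(1, fout)
      layers[[l]]$beta <- rep(0, fout)
      layers[[l]]$run_mean <- rep(0, fout)
      layers[[l]]$run_var <- rep(1, fout)
    }
  }
  structure(list(widths = widths, layers = layers, cfg = cfg,
                 trained = FALSE),
            class = "tfo_mlp")
}

#' Parameter count of a fusion network
#'
#' Weights + biases of every linear layer plus the scale/shift pairs of each
#' batch-normalized hidden block (running statistics are not parameters).
#'
#' @param model A `tfo_mlp`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  w <- model$widths
  nh <- length(w) - 2
  lin <- sum(w[-length(w)] * w[-1]) + sum(w[-1])
  bn <- 2 * sum(w[2:(nh + 1)])
  lin + bn
}

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

mlp_forward <- function(model, X, training = FALSE) {
  nh <- length(model$widths) - 2
  cache <- vector("list", nh)
  bn_post <- model$cfg$bn_after_activation
  A <- X
  for (l in seq_len(nh)) {
    ly <- model$layers[[l]]
    H <- sweep(A %*% ly$W, 2, ly$b, "+")
    bn_apply <- function(Z) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(sweep(Z, 2, mu)^2)
        model$layers[[l]]$run_mean <<-
          (1 - .BN_MOMENTUM) * ly$run_mean + .BN_MOMENTUM * mu
        model$layers[[l]]$run_var <<-
          (1 - .BN_MOMENTUM) * ly$run_var + .BN_MOMENTUM * v
      } else {
        mu <- ly$run_mean; v <- ly$run_var
      }
      std <- sqrt(v + .BN_EPS)
      Xhat <- sweep(sweep(Z, 2, mu), 2, std, "/")
      list(out = sweep(sweep(Xhat, 2, ly$gamma, "*"), 2, ly$beta, "+"),
           Xhat = Xhat, std = std)
    }
    if (bn_post) {
      Arelu <- pmax(H, 0)
      bn <- bn_apply(Arelu)
      cache[[l]] <- list(A_in = A, H = H, Arelu = Arelu,
                         Xhat = bn$Xhat, std = bn$std)
      A <- bn$out
    } else {
      bn <- bn_apply(H)
      Arelu <- pmax(bn$out, 0)
      cache[[l]] <- list(A_in = A, H = H, bn_out = bn$out,
                         Xhat = bn$Xhat, std = bn$std)
      A <- Arelu
    }
  }
  out_l <- model$layers[[nh + 1]]
  pred <- drop(sweep(A %*% out_l$W, 2, out_l$b, "+"))
  list(pred = pred, A_last = A, cache = cache, model = model)
}

bn_backward <- function(dY, Xhat, std, gamma) {
  B <- nrow(dY)
  dgamma <- colSums(dY * Xhat)
  dbeta <- colSums(dY)
  dXhat <- sweep(dY, 2, gamma, "*")
  dZ <- sweep(dXhat - matrix(colMeans(dXhat), B, ncol(dY), byrow = TRUE) -
                Xhat * matrix(colMeans(dXhat * Xhat), B, ncol(dY), byrow = TRUE),
              2, std, "/")
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

mlp_backward <- function(model, fw, dpred) {
  nh <- length(model$widths) - 2
  grads <- vector("list", nh + 1)
  out_l <- model$layers[[nh + 1]]
  dpred <- matrix(dpred, ncol = 1)
  grads[[nh + 1]] <- list(W = t(fw$A_last) %*% dpred, b = colSums(dpred))
  dA <- dpred %*% t(out_l$W)
  bn_post <- model$cfg$bn_after_activation
  for (l in rev(seq_len(nh))) {
    ly <- model$layers[[l]]
    cc <- fw$cache[[l]]
    if (bn_post) {
      bb <- bn_backward(dA, cc$Xhat, cc$std, ly$gamma)
      dH <- bb$dZ * (cc$H > 0)
    } else {
      dBnOut <- dA * (cc$bn_out > 0)
      bb <- bn_backward(dBnOut, cc$Xhat, cc$std, ly$gamma)
      dH <- bb$dZ
    }
    grads[[l]] <- list(W = t(cc$A_in) %*% dH, b = colSums(dH),
                       gamma = bb$dgamma, beta = bb$dbeta)
    if (l > 1) dA <- dH %*% t(ly$W)
  }
  grads
}

adam_state <- function(model) {
  lapply(model$layers, function(ly) {
    keep <- intersect(names(ly), c("W", "b", "gamma", "beta"))
    lapply(setNames(keep, keep), function(nm) {
      list(m = ly[[nm]] * 0, v = ly[[nm]] * 0)
    })
  })
}

adam_update <- function(model, grads, state, step, lr, wd,
                        b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (l in seq_along(grads)) {
    for (nm in names(state[[l]])) {
      g <- grads[[l]][[nm]]
      if (nm == "W") g <- g + wd * model$layers[[l]][[nm]]
      st <- state[[l]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^step)
      vhat <- st$v / (1 - b2^step)
      model$layers[[l]][[nm]] <- model$layers[[l]][[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[l]][[nm]] <- st
    }
  }
  list(model = model, state = state)
}

# weighted-MSE training loop with early stopping; X/y matrices, w weights.
# Features and labels are standardized on the training statistics (stored in
# the model, undone at prediction) so the published optimizer settings are
# meaningful regardless of the raw feature/label scale.
mlp_train <- function(model, X_tr, y_tr, X_val, y_val, w_tr = NULL) {
  cfg <- model$cfg
  n <- nrow(X_tr)
  w_tr <- w_tr %||% rep(1, n)
  model$x_center <- colMeans(X_tr)
  model$x_scale <- pmax(apply(X_tr, 2, sd), 1e-12)
  model$y_center <- mean(y_tr)
  model$y_scale <- max(sd(y_tr), 1e-12)
  std_x <- function(X) sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  X_tr <- std_x(X_tr); X_val <- std_x(X_val)
  y_tr <- (y_tr - model$y_center) / model$y_scale
  y_val <- (y_val - model$y_center) / model$y_scale
  state <- adam_state(model)
  step <- 0
  best <- list(loss = Inf, layers = model$layers, epoch = 0)
  history <- numeric(0)
  set.seed(cfg$seed + 1)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      if (length(idx) < 2) next  # batch statistics need >= 2 samples
      fw <- mlp_forward(model, X_tr[idx, , drop = FALSE], training = TRUE)
      model <- fw$model
      resid <- fw$pred - y_tr[idx]
      if (any(!is.finite(resid))) {
        abort("Training diverged: non-finite loss.", class = "tfo_error_training",
              history = history)
      }
      dpred <- 2 * w_tr[idx] * resid / length(idx)
      grads <- mlp_backward(model, fw, dpred)
      step <- step + 1
      up <- adam_update(model, grads, state, step, cfg$lr, cfg$weight_decay)
      model <- up$model; state <- up$state
    }
    val_pred <- mlp_forward(model, X_val, training = FALSE)$pred
    val_loss <- mean((val_pred - y_val)^2)
    history <- c(history, val_loss)
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, layers = model$layers, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$patience) {
      break
    }
  }
  model$layers <- best$layers
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best$epoch
  model
}

#' Predict with a fusion network
#'
#' @param object A trained `tfo_mlp`.
#' @param newdata Numeric matrix or data frame of features (columns in
#'   training order).
#' @param ... Unused.
#' @return Numeric predictions (fSpO2, percent).
#' @export
predict.tfo_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$x_center)) {
    X <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  }
  pred <- mlp_forward(object, X, training = FALSE)$pred
  if (!is.null(object$y_center)) pred <- pred * object$y_scale + object$y_center
  pred
}
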