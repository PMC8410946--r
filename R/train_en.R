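# Exact spectral-l1 regularized training: the model's full combinatorial
# landscape is enumerated at every update step, transformed, and the l1
# norm of the (unitary-scale) spectrum is added to the squared-error loss.
# The penalty gradient with respect to the landscape values is
# alpha * 2^(-d/2) * H sign(u) (subgradient 0 at exactly-zero coefficients),
# which the same butterfly computes in O(p log p).

#' Training configuration for exact spectral-l1 training
#'
#' @param alpha spectral penalty weight (>= 0); 0.1 is the calibrated
#'   default for the unitary-scale penalty.
#' @param lr Adam learning rate; 0.01 for regularized training, 0.001 for
#'   the unregularized baseline.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param batch_size minibatch size for the squared-error term; the penalty
#'   always sees the full 2^d landscape.
#' @param d_max scalability refusal boundary for full enumeration.
#' @param divergence_factor abort training once validation MSE exceeds this
#'   multiple of the best validation MSE seen (the optimizer has left the
#'   useful regime); the best-validation parameters are still returned.
#' @param seed seed controlling initialization and batch shuffling.
#' @return an `en_config` list.
#' @export
en_config <- function(alpha = 0.1, lr = 0.01, epochs = 1000L, patience = 20L,
                      batch_size = 64L, d_max = MAX_DENSE_D,
                      divergence_factor = 5, seed = 1L) {
  stopifnot(alpha >= 0, lr > 0, epochs >= 0, patience >= 1, batch_size >= 1,
            divergence_factor > 1)
  structure(list(alpha = alpha, lr = lr, epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 d_max = as.integer(d_max),
                 divergence_factor = divergence_factor,
                 seed = as.integer(seed)),
            class = "en_config")
}

# unitary spectrum of the model landscape as a bare vector (index order)
model_spectrum_raw <- function(model, X_all) {
  g <- dnn_forward(model, X_all)$y
  list(g = g, u = fwht_core(g) / 2^(model$d / 2))
}

#' Composite spectral-l1 training loss
#'
#' `sum_i (y_i - g(x_i))^2 + alpha * || H g(X) ||_1` with H unitary.
#'
#' @param model a `wh_dnn`.
#' @param batch_x n x d +/-1 matrix.
#' @param batch_y length-n responses.
#' @param alpha penalty weight.
#' @param d_max refusal boundary (enumeration is exponential in d).
#' @return scalar loss.
#' @export
en_loss <- function(model, batch_x, batch_y, alpha, d_max = MAX_DENSE_D) {
  if (model$d > d_max) {
    stop("d = ", model$d, " exceeds d_max = ", d_max,
         ": exact spectral training does not scale; use train_ens()")
  }
  mse <- sum((batch_y - predict(model, batch_x))^2)
  if (alpha == 0) return(mse)
  X_all <- enumerate_inputs(model$d, d_max)
  u <- model_spectrum_raw(model, X_all)$u
  mse + alpha * sum(abs(u))
}

#' Train with the exact spectral-l1 penalty
#'
#' Joint Adam optimization of the squared error on the training data plus
#' `alpha` times the l1 norm of the unitary WH spectrum of the model's full
#' landscape, re-enumerated at every update step. Early stopping monitors
#' penalty-free validation MSE; the best-validation parameters are returned.
#'
#' @param model a `wh_dnn` (or `NULL` to build one from `d`, `f`, seed).
#' @param train_x,train_y training inputs (+/-1 matrix) and responses.
#' @param val_x,val_y validation set for early stopping.
#' @param config an [en_config()].
#' @return list with the trained `model` and `log` (a data.frame with
#'   per-epoch train MSE, spectral l1, composite loss, validation MSE) plus
#'   `best_epoch`.
#' @export
train_en <- function(model, train_x, train_y, val_x, val_y,
                     config = en_config()) {
  stopifnot(inherits(model, "wh_dnn"), nrow(train_x) == length(train_y))
  d <- model$d
  if (config$alpha > 0 && d > config$d_max) {
    stop("d = ", d, " exceeds d_max = ", config$d_max,
         ": exact spectral training does not scale; use train_ens()")
  }
  X_all <- if (config$alpha > 0) enumerate_inputs(d, config$d_max) else NULL
  n <- nrow(train_x)
  set.seed(config$seed)
  best <- list(val = Inf, params = model$params, running = model$running,
               epoch = 0L)
  log_rows <- vector("list", config$epochs)
  wait <- 0L
  scale_u <- 2^(-d / 2)
  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    for (bi in batches) {
      cache <- dnn_forward(model, train_x[bi, , drop = FALSE], train = TRUE)
      model <- dnn_update_running(model, cache)
      dy <- -2 * (train_y[bi] - cache$y)
      grads <- dnn_backward(model, cache, dy)
      if (config$alpha > 0) {
        # penalty on the population-mode landscape: the enumerated batch is
        # the full input space, so its batch statistics are the population
        # statistics (the standard autodiff-through-batchnorm semantics)
        cache_all <- dnn_forward(model, X_all, train = TRUE)
        u <- fwht_core(cache_all$y) * scale_u
        dy_pen <- config$alpha * scale_u * fwht_core(sign(u))
        grads <- grads_add(grads, dnn_backward(model, cache_all, dy_pen))
      }
      model <- dnn_adam_step(model, grads, config$lr)
    }
    train_pred <- predict(model, train_x)
    train_mse <- mean((train_y - train_pred)^2)
    pen_l1 <- if (config$alpha > 0) {
      sum(abs(fwht_core(predict(model, X_all)) * scale_u))
    } else 0
    composite <- sum((train_y - train_pred)^2) + config$alpha * pen_l1
    val_mse <- mean((val_y - predict(model, val_x))^2)
    if (!is.finite(composite) || !is.finite(val_mse)) {
      stop("non-finite loss at epoch ", epoch,
           " (train MSE = ", train_mse, ", penalty = ", pen_l1, ")")
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, train_mse = train_mse,
                                    spectral_l1 = pen_l1,
                                    composite = composite, val_mse = val_mse)
    if (val_mse < best$val - 1e-12) {
      best <- list(val = val_mse, params = model$params,
                   running = model$running, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
      if (val_mse > config$divergence_factor * best$val) break
    }
  }
  model_final <- model
  model$params <- best$params
  model$running <- best$running
  log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  list(model = model, model_final = model_final, log = log,
       best_epoch = best$epoch)
}

#' Full WH spectrum of a trained model
#'
#' Enumerates the model landscape and transforms it.
#'
#' @param model a `wh_dnn` with `d <= d_max`.
#' @param scale output scale.
#' @param d_max enumeration refusal boundary.
#' @return a dense `wh_spectrum`.
#' @export
model_spectrum <- function(model, scale = c("multilinear", "unitary"),
                           d_max = MAX_DENSE_D) {
  X_all <- enumerate_inputs(model$d, d_max)
  fwht(wh_landscape(predict(model, X_all), model$d), match.arg(scale))
}
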