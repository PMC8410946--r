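# Four-layer fully connected network (d -> fd -> fd -> d -> 1) with batch
# normalization and leaky ReLU on the hidden layers, Xavier-uniform
# initialization and Adam updates. Implemented as explicit forward/backward
# passes on BLAS matmuls: the spectral penalties below need the gradient of
# arbitrary scalar losses with respect to the network outputs at arbitrary
# input batches, which a closed hand-written backward provides exactly.
#
# Training passes normalize by the statistics of the batch being pushed
# (the data batch, or the enumerated/subsampled landscape batch for the
# spectral terms); prediction uses running averages accumulated from data
# batches only.

LEAKY_SLOPE <- 0.01
BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

xavier_uniform <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), nrow = n_in, ncol = n_out)
}

#' Build the sequence-to-fitness network
#'
#' Layer widths d x fd, fd x fd, fd x d, d x 1; batch normalization and
#' leaky-ReLU activations on the three hidden layers; Xavier-uniform
#' weights, zero biases, unit batch-norm gains. Identical seeds give
#' identical parameters, hence identical predictions.
#'
#' @param d input width (number of binary features).
#' @param f expansion factor (>= 1); use 1 for very large d.
#' @param seed RNG seed for the initialization.
#' @param batchnorm disable to get a plain leaky-ReLU multilayer perceptron.
#' @return an object of class `wh_dnn`.
#' @export
build_dnn <- function(d, f = 10L, seed = 1L, batchnorm = TRUE) {
  stopifnot(d >= 1, f >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  dims <- list(c(d, f * d), c(f * d, f * d), c(f * d, d), c(d, 1))
  params <- list()
  for (l in seq_along(dims)) {
    params[[paste0("W", l)]] <- xavier_uniform(dims[[l]][1], dims[[l]][2])
    params[[paste0("b", l)]] <- numeric(dims[[l]][2])
    if (batchnorm && l < 4) {
      params[[paste0("g", l)]] <- rep(1, dims[[l]][2])
      params[[paste0("s", l)]] <- numeric(dims[[l]][2])
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  running <- if (batchnorm) {
    lapply(1:3, function(l) list(mean = numeric(dims[[l]][2]),
                                 var = rep(1, dims[[l]][2]),
                                 initialized = FALSE))
  } else NULL
  adam <- list(m = lapply(params, function(p) p * 0),
               v = lapply(params, function(p) p * 0), t = 0L)
  structure(list(d = as.integer(d), f = as.integer(f), seed = as.integer(seed),
                 batchnorm = batchnorm, params = params, running = running,
                 adam = adam), class = "wh_dnn")
}

leaky <- function(z) ifelse(z > 0, z, LEAKY_SLOPE * z)
leaky_grad <- function(z) ifelse(z > 0, 1, LEAKY_SLOPE)

# one hidden layer forward: linear (+ batchnorm) + leaky ReLU
layer_forward <- function(model, l, A_in, train) {
  p <- model$params
  Z <- sweep(A_in %*% p[[paste0("W", l)]], 2, p[[paste0("b", l)]], "+")
  if (!model$batchnorm) {
    return(list(A = leaky(Z), Z = Z))
  }
  if (train && nrow(Z) > 1) {
    mu <- colMeans(Z)
    va <- colMeans(Z^2) - mu^2
  } else {
    mu <- model$running[[l]]$mean
    va <- model$running[[l]]$var
  }
  inv_std <- 1 / sqrt(va + BN_EPS)
  Zh <- sweep(sweep(Z, 2, mu, "-"), 2, inv_std, "*")
  Y <- sweep(sweep(Zh, 2, p[[paste0("g", l)]], "*"), 2,
             p[[paste0("s", l)]], "+")
  list(A = leaky(Y), Z = Z, Zh = Zh, Y = Y, mu = mu, inv_std = inv_std)
}

# forward pass; keeps intermediates for the backward pass
dnn_forward <- function(model, X, train = FALSE) {
  l1 <- layer_forward(model, 1, X, train)
  l2 <- layer_forward(model, 2, l1$A, train)
  l3 <- layer_forward(model, 3, l2$A, train)
  y <- as.numeric(sweep(l3$A %*% model$params$W4, 2, model$params$b4, "+"))
  list(y = y, X = X, l1 = l1, l2 = l2, l3 = l3, train = train)
}

# update running batch statistics from a data-batch cache (train = TRUE)
dnn_update_running <- function(model, cache) {
  if (!model$batchnorm) return(model)
  for (l in 1:3) {
    lc <- cache[[paste0("l", l)]]
    r <- model$running[[l]]
    va <- 1 / lc$inv_std^2 - BN_EPS
    if (!r$initialized) {
      r$mean <- lc$mu; r$var <- va; r$initialized <- TRUE
    } else {
      r$mean <- BN_MOMENTUM * r$mean + (1 - BN_MOMENTUM) * lc$mu
      r$var <- BN_MOMENTUM * r$var + (1 - BN_MOMENTUM) * va
    }
    model$running[[l]] <- r
  }
  model
}

#' Predict fitness values
#'
#' Uses the accumulated running batch statistics (evaluation mode).
#'
#' @param object a `wh_dnn`.
#' @param X n x d matrix of +/-1 inputs.
#' @param ... unused.
#' @return numeric vector of n predictions.
#' @export
predict.wh_dnn <- function(object, X, ...) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  dnn_forward(object, X, train = FALSE)$y
}

# backward through one hidden layer; dA is dLoss/dA. Returns dLoss/dA_in
# and writes this layer's parameter gradients into `acc`.
layer_backward <- function(model, l, lc, A_in, dA, acc) {
  p <- model$params
  if (!model$batchnorm) {
    dZ <- dA * leaky_grad(lc$Z)
  } else {
    dY <- dA * leaky_grad(lc$Y)
    acc[[paste0("g", l)]] <- colSums(dY * lc$Zh)
    acc[[paste0("s", l)]] <- colSums(dY)
    dZh <- sweep(dY, 2, p[[paste0("g", l)]], "*")
    if (isTRUE(lc$batch_stats)) {
      m <- nrow(dZh)
      dZ <- sweep(dZh - matrix(colMeans(dZh), m, ncol(dZh), byrow = TRUE) -
                    sweep(lc$Zh, 2, colMeans(dZh * lc$Zh), "*"),
                  2, lc$inv_std, "*")
    } else {
      dZ <- sweep(dZh, 2, lc$inv_std, "*")   # frozen (running) statistics
    }
  }
  acc[[paste0("W", l)]] <- crossprod(A_in, dZ)
  acc[[paste0("b", l)]] <- colSums(dZ)
  acc$.dA_in <- dZ %*% t(p[[paste0("W", l)]])
  acc
}

# backward pass: dy is dLoss/dy (length n); returns gradient list
dnn_backward <- function(model, cache, dy) {
  p <- model$params
  train_stats <- cache$train && length(dy) > 1
  for (l in 1:3) cache[[paste0("l", l)]]$batch_stats <- train_stats
  D4 <- matrix(dy, ncol = 1)
  acc <- list(W4 = crossprod(cache$l3$A, D4), b4 = colSums(D4))
  dA3 <- D4 %*% t(p$W4)
  acc <- layer_backward(model, 3, cache$l3, cache$l2$A, dA3, acc)
  acc <- layer_backward(model, 2, cache$l2, cache$l1$A, acc$.dA_in, acc)
  acc <- layer_backward(model, 1, cache$l1, cache$X, acc$.dA_in, acc)
  acc$.dA_in <- NULL
  acc[names(model$params)]
}

grads_add <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  Map(`+`, g1, g2)
}

# one Adam step; returns the updated model
dnn_adam_step <- function(model, grads, lr, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8) {
  ad <- model$adam
  ad$t <- ad$t + 1L
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    ad$m[[nm]] <- beta1 * ad$m[[nm]] + (1 - beta1) * g
    ad$v[[nm]] <- beta2 * ad$v[[nm]] + (1 - beta2) * g^2
    mhat <- ad$m[[nm]] / (1 - beta1^ad$t)
    vhat <- ad$v[[nm]] / (1 - beta2^ad$t)
    model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  model$adam <- ad
  model
}

#' @export
print.wh_dnn <- function(x, ...) {
  cat(sprintf(
    "fitness network: d = %d, f = %d (%d -> %d -> %d -> %d -> 1)%s\n",
    x$d, x$f, x$d, x$f * x$d, x$f * x$d, x$d,
    if (x$batchnorm) ", batchnorm" else ""))
  invisible(x)
}
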