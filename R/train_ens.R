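# Scalable spectral training: ADMM alternation between (1) Adam updates of
# the network on the data loss plus a quadratic coupling at the subsampled
# query points X_T, (2) a sparse-spectrum update solved by the peeling
# decoder on g(X_T) + gamma with an l0 hard threshold, and (3) the dual
# update. Everything touches only n + |T| model evaluations; no object of
# size 2^d is ever created, so d can far exceed the exact pathway's limit.
#
# u is kept on the unitary scale (u = H g with H unitary), matching the
# exact penalty; H_T u is evaluated on the fly from u's support.

#' Configuration for ADMM spectral training
#'
#' @param alpha sparsity weight of the u-step (calibrated default 1).
#' @param rho ADMM coupling weight (> 0; calibrated default 0.01).
#' @param outer_iterations number of ADMM iterations.
#' @param sgd_epochs Adam epochs per theta-step.
#' @param lr Adam learning rate.
#' @param C,b,k_estimate,plan_seed sampling-plan parameters
#'   (see [design_plan()]).
#' @param batch_size minibatch size for the data term.
#' @param divergence_factor abort the outer loop once validation MSE
#'   exceeds this multiple of the best seen; best parameters are returned.
#' @param warmstart_epochs data-only Adam epochs (with validation-based
#'   checkpointing) before the ADMM loop; the alternation starts from the
#'   maximum-likelihood-trained network rather than from random weights, so
#'   the first spectral projection sees a fitted landscape.
#' @param u_threshold how alpha enters the sparse projection: `"prox"`
#'   (default) hard-thresholds recovered coefficients at
#'   u^2 >= 2 alpha / rho, the exact l0 proximal rule; `"peel"` lets the
#'   decoder's noise-adaptive singleton detection alone carry the l0
#'   structure.
#' @param seed seed for shuffling.
#' @return an `ens_config` list.
#' @export
ens_config <- function(alpha = 1, rho = 0.01, outer_iterations = 20L,
                       sgd_epochs = 50L, lr = 0.01, C = 3L, b = NULL,
                       k_estimate = 25L, plan_seed = 1L, batch_size = 64L,
                       divergence_factor = 5, warmstart_epochs = 300L,
                       u_threshold = c("prox", "peel"), seed = 1L) {
  stopifnot(alpha >= 0, rho > 0, outer_iterations >= 0, sgd_epochs >= 1,
            divergence_factor > 1)
  structure(list(alpha = alpha, rho = rho,
                 outer_iterations = as.integer(outer_iterations),
                 sgd_epochs = as.integer(sgd_epochs), lr = lr,
                 C = as.integer(C), b = b, k_estimate = as.integer(k_estimate),
                 plan_seed = as.integer(plan_seed),
                 batch_size = as.integer(batch_size),
                 divergence_factor = divergence_factor,
                 warmstart_epochs = as.integer(warmstart_epochs),
                 u_threshold = match.arg(u_threshold),
                 seed = as.integer(seed)),
            class = "ens_config")
}

#' Evaluate H_T u on the fly from a sparse spectrum
#'
#' Row for query x is `sum_S u_S * s(d) * prod_{i in S} x_i`, with s(d) the
#' scale factor that makes the result the landscape value (2^(-d/2) for a
#' unitary-scale u, 1 for multilinear). Cost O(|T| * |supp(u)|).
#'
#' @param X |T| x d +/-1 query matrix.
#' @param u a sparse `wh_spectrum`.
#' @return numeric vector of length |T|.
#' @export
ht_times_u <- function(X, u) {
  stopifnot(inherits(u, "wh_spectrum"))
  if (length(u$coefficients) == 0) return(numeric(nrow(X)))
  fac <- if (u$scale == "unitary") 2^(-u$d / 2) else 1
  eval_pbf(pbf(names(u$coefficients),
               unname(u$coefficients) * fac, u$d), X)
}

#' ADMM theta-step: data loss plus quadratic spectral coupling
#'
#' Runs `sgd_epochs` Adam epochs on
#' `sum_i (y_i - g(x_i))^2 + (rho/2) * ||g(X_T) - H_T u + gamma||^2`.
#'
#' @param model a `wh_dnn`.
#' @param train_x,train_y training data.
#' @param X_T subsampled query matrix.
#' @param u current sparse spectrum (unitary scale).
#' @param gamma dual vector of length |T|.
#' @param rho coupling weight.
#' @param config an `ens_config` (epochs, lr, batch size).
#' @param val_x,val_y optional validation set: when given, validation MSE
#'   is recorded after every epoch and the per-epoch best checkpoint is
#'   returned alongside the final state (model selection runs at the same
#'   granularity as the exact path).
#' @return the updated model; with a validation set, a list with `model`
#'   (final state, continuing the ADMM trajectory), `best` (checkpoint with
#'   `val`, `params`, `running`) and `val_trace`.
#' @export
theta_step <- function(model, train_x, train_y, X_T, u, gamma, rho, config,
                       val_x = NULL, val_y = NULL) {
  stopifnot(length(gamma) == nrow(X_T))
  target <- ht_times_u(X_T, u) - gamma  # penalty = (rho/2)||g(X_T) - target||^2
  n <- nrow(train_x)
  track <- !is.null(val_x)
  best <- list(val = Inf, params = NULL, running = NULL)
  val_trace <- numeric(0)
  for (ep in seq_len(config$sgd_epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    for (bi in batches) {
      cache <- dnn_forward(model, train_x[bi, , drop = FALSE], train = TRUE)
      model <- dnn_update_running(model, cache)
      grads <- dnn_backward(model, cache, -2 * (train_y[bi] - cache$y))
      if (rho > 0) {
        # coupling on the prediction-mode values (frozen batch statistics)
        cache_t <- dnn_forward(model, X_T, train = FALSE)
        grads <- grads_add(grads,
                           dnn_backward(model, cache_t,
                                        rho * (cache_t$y - target)))
      }
      model <- dnn_adam_step(model, grads, config$lr)
    }
    if (track) {
      v <- mean((val_y - predict(model, val_x))^2)
      val_trace <- c(val_trace, v)
      if (v < best$val) {
        best <- list(val = v, params = model$params, running = model$running)
      }
    }
  }
  if (track) list(model = model, best = best, val_trace = val_trace)
  else model
}

#' ADMM u-step: sparse spectral projection by peeling
#'
#' Peels `w = g(X_T) + gamma` through the plan's sparse-graph code;
#' optionally hard-thresholds the result by the exact proximal rule for
#' `alpha ||u||_0 + (rho/2) ||w - H_T u||^2` on an orthonormal basis (keep
#' a coefficient iff u_S^2 >= 2 alpha / rho).
#'
#' @param w numeric vector g(X_T) + gamma aligned with the plan's points.
#' @param points output of [sample_points()] for `plan`.
#' @param plan the `sampling_plan`.
#' @param alpha,rho thresholding parameters.
#' @param previous_u fallback returned when peeling diverges entirely.
#' @param apply_threshold apply the proximal hard threshold (see
#'   `u_threshold` in [ens_config()] for the trade-off).
#' @return list with `u` (sparse unitary-scale spectrum) and the
#'   `recovery_result`.
#' @export
u_step <- function(w, points, plan, alpha, rho, previous_u = NULL,
                   apply_threshold = TRUE) {
  res <- peel(compute_observations(w, points, plan), plan)
  multi <- res$spectrum
  u_co <- multi$coefficients * 2^(plan$d / 2)  # multilinear -> unitary
  if (apply_threshold && alpha > 0) u_co <- u_co[u_co^2 >= 2 * alpha / rho]
  u <- wh_spectrum(u_co, plan$d, "unitary")
  if (!res$converged && length(u_co) == 0 && !is.null(previous_u)) {
    u <- previous_u
  }
  list(u = u, recovery = res)
}

#' ADMM dual update
#'
#' `gamma <- gamma + g(X_T) - H_T u`: plain addition of the primal residual.
#'
#' @param gamma dual vector.
#' @param g_xt model values on X_T.
#' @param ht_u H_T u values (same length).
#' @return updated gamma.
#' @export
dual_step <- function(gamma, g_xt, ht_u) {
  stopifnot(length(gamma) == length(g_xt), length(gamma) == length(ht_u))
  gamma + (g_xt - ht_u)
}

#' Train with the scalable ADMM spectral penalty
#'
#' Fixes a sampling plan once, initializes u = 0 and gamma = 0, then loops
#' theta-step -> u-step (peeling) -> dual update for the configured outer
#' iterations. Early model selection uses penalty-free validation MSE. With
#' zero outer iterations this reduces to plain (data-only) training.
#'
#' @param model a `wh_dnn`.
#' @param train_x,train_y,val_x,val_y data (+/-1 matrices, responses).
#' @param config an [ens_config()].
#' @return list: best-validation `model`, `trace` data.frame (iteration,
#'   primal residual, support size, validation MSE), `u_history` (list of
#'   sparse spectra), final `u`, `gamma`, and the `plan`.
#' @export
train_ens <- function(model, train_x, train_y, val_x, val_y,
                      config = ens_config()) {
  stopifnot(inherits(model, "wh_dnn"))
  d <- model$d
  plan <- design_plan(d, config$k_estimate, C = config$C, b = config$b,
                      seed = config$plan_seed)
  pts <- sample_points(plan)     # cached for every ADMM iteration
  if (config$warmstart_epochs > 0) {
    warm <- train_en(model, train_x, train_y, val_x, val_y,
                     en_config(alpha = 0, lr = config$lr,
                               epochs = config$warmstart_epochs,
                               patience = max(config$warmstart_epochs %/% 2L,
                                              1L),
                               batch_size = config$batch_size,
                               divergence_factor = config$divergence_factor,
                               seed = config$seed))
    model <- warm$model
  }
  set.seed(config$seed)
  u <- wh_spectrum(numeric(0), d, "unitary")
  gamma <- numeric(pts$n_queries)
  if (config$warmstart_epochs > 0 && config$outer_iterations > 0) {
    # u0 = unthresholded spectral projection of the warm-started landscape:
    # the constraint starts near-satisfied (instead of dragging g(X_T) to
    # zero), and the coupling first concentrates the model onto the peeled
    # skeleton so amplitudes can grow past the proximal threshold
    u <- u_step(predict(model, pts$X), pts, plan, config$alpha, config$rho,
                previous_u = u, apply_threshold = FALSE)$u
  }
  best <- list(val = mean((val_y - predict(model, val_x))^2),
               params = model$params, running = model$running, iter = 0L)
  u_history <- list()
  trace <- vector("list", config$outer_iterations)
  if (config$outer_iterations == 0 && config$warmstart_epochs == 0) {
    # data-only training with the same budget shape
    model <- theta_step(model, train_x, train_y, pts$X, u, gamma, 0, config)
    best <- list(val = mean((val_y - predict(model, val_x))^2),
                 params = model$params, running = model$running, iter = 0L)
  }
  for (it in seq_len(config$outer_iterations)) {
    ts <- theta_step(model, train_x, train_y, pts$X, u, gamma,
                     config$rho, config, val_x = val_x, val_y = val_y)
    model <- ts$model
    if (ts$best$val < best$val - 1e-12) {
      best <- list(val = ts$best$val, params = ts$best$params,
                   running = ts$best$running, iter = it)
    }
    g_xt <- predict(model, pts$X)
    st <- u_step(g_xt + gamma, pts, plan, config$alpha, config$rho,
                 previous_u = u,
                 apply_threshold = config$u_threshold == "prox")
    u <- st$u
    ht_u <- ht_times_u(pts$X, u)
    gamma <- dual_step(gamma, g_xt, ht_u)
    resid <- sqrt(sum((g_xt - ht_u)^2))
    val_mse <- mean((val_y - predict(model, val_x))^2)
    if (!is.finite(val_mse)) stop("non-finite validation loss at iteration ", it)
    u_history[[it]] <- u
    trace[[it]] <- data.frame(iteration = it, primal_residual = resid,
                              support = length(u$coefficients),
                              recovery_converged = st$recovery$converged,
                              val_mse = val_mse)
    if (val_mse < best$val - 1e-12) {
      best <- list(val = val_mse, params = model$params,
                   running = model$running, iter = it)
    } else if (val_mse > config$divergence_factor * best$val) {
      break
    }
  }
  model$params <- best$params
  model$running <- best$running
  list(model = model,
       trace = if (length(trace)) do.call(rbind, trace) else NULL,
       u_history = u_history, u = u, gamma = gamma, plan = plan,
       queries = pts$n_queries, best_iteration = best$iter)
}

#' Histogram of interaction orders across recovered spectra
#'
#' Counts the subset sizes |S| of every coefficient recovered across the
#' ADMM iterations (or any list of spectra).
#'
#' @param u_history nonempty list of `wh_spectrum` objects.
#' @return named integer vector: count per interaction order.
#' @export
order_histogram <- function(u_history) {
  if (inherits(u_history, "wh_spectrum")) u_history <- list(u_history)
  stopifnot(length(u_history) > 0)
  orders <- unlist(lapply(u_history, function(u) {
    mask_order(names(u$coefficients))
  }))
  if (length(orders) == 0) return(integer(0))
  table(factor(orders, levels = 0:max(orders)))
}

#' Soft-thresholding proximal operator (reference utility)
#'
#' The prox of `alpha ||u||_1 + (rho/2) ||w - u||^2`, i.e. elementwise
#' shrinkage of w by `alpha / rho`. Not on the ADMM main path (the peeling
#' decoder with the l0 hard threshold replaces it); provided as the
#' l1-relaxed reference.
#'
#' @param w numeric vector.
#' @param alpha,rho threshold parameters (threshold = alpha / rho).
#' @return thresholded vector.
#' @export
soft_threshold <- function(w, alpha, rho) {
  thr <- alpha / rho
  sign(w) * pmax(abs(w) - thr, 0)
}
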