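# Evaluation: coefficient of determination, spectrum NMSE, the
# Lasso-over-WH-monomials baseline with OLS debiasing, and the paired
# benchmark orchestrator.

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return R-squared (can be negative for bad predictors).
#' @export
r_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("zero variance in y_true")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Normalized mean squared error between spectra
#'
#' `||est - truth||^2 / ||truth||^2` over the union of stored supports
#' (missing coefficients are zero). Both spectra must share d; scales are
#' aligned by converting the estimate to the truth's scale.
#'
#' @param estimated,truth `wh_spectrum` objects.
#' @return nonnegative real.
#' @export
spectrum_nmse <- function(estimated, truth) {
  stopifnot(inherits(estimated, "wh_spectrum"), inherits(truth, "wh_spectrum"),
            estimated$d == truth$d)
  estimated <- convert_scale(estimated, truth$scale)
  energy <- sum(truth$coefficients^2)
  if (energy == 0) stop("zero-energy truth spectrum")
  support <- union(names(estimated$coefficients), names(truth$coefficients))
  e <- numeric(length(support)); names(e) <- support
  t_ <- e
  e[names(estimated$coefficients)] <- estimated$coefficients
  t_[names(truth$coefficients)] <- truth$coefficients
  sum((e - t_)^2) / energy
}

# all masks of order 1..max_order, in deterministic order
masks_up_to_order <- function(d, max_order) {
  unlist(lapply(seq_len(max_order), function(o) {
    combn(d, o, function(s) mask_from_sites(s, d))
  }))
}

# WH monomial feature matrix for the given masks
monomial_features <- function(X, masks) {
  neg <- X < 0
  F <- vapply(masks, function(m) {
    sites <- sites_from_mask(m)
    1 - 2 * (rowSums(neg[, sites, drop = FALSE]) %% 2)
  }, numeric(nrow(X)))
  matrix(F, nrow = nrow(X), dimnames = list(NULL, masks))
}

#' Lasso over WH monomial features with OLS debiasing
#'
#' Builds the monomial feature matrix up to `max_order`, fits the l1 path
#' over `lambda_grid` (50 log-spaced values on [1e-7, 1] by default), then
#' for each candidate top-m support refits by ordinary least squares and
#' selects (lambda, m) by validation MSE. Plain Lasso is included in the
#' search (m = all nonzero).
#'
#' @param train_x,train_y training data (+/-1 inputs).
#' @param val_x,val_y validation data for model selection.
#' @param max_order maximum interaction order of the features (1 or 2 in
#'   typical use; feature count is sum_o choose(d, o)).
#' @param lambda_grid penalty grid.
#' @param top_m_grid candidate support sizes for the OLS refit; `Inf` means
#'   all nonzero coefficients.
#' @return list: `model` (a `pbf` including the intercept term), `report`
#'   (chosen lambda, m, validation MSE), and `predict(X)`.
#' @export
lasso_wh_baseline <- function(train_x, train_y, val_x, val_y, max_order = 2L,
                              lambda_grid = 10^seq(log10(1e-7), 0,
                                                   length.out = 50),
                              top_m_grid = c(1, 2, 5, 10, 20, 50, Inf)) {
  d <- ncol(train_x)
  masks <- masks_up_to_order(d, max_order)
  Ftr <- monomial_features(train_x, masks)
  Fva <- monomial_features(val_x, masks)
  fit <- glmnet::glmnet(Ftr, train_y, alpha = 1,
                        lambda = sort(lambda_grid, decreasing = TRUE),
                        standardize = FALSE, intercept = TRUE)
  coefs <- as.matrix(stats::coef(fit))  # (1+p) x nlambda
  best <- list(mse = Inf, beta = NULL, lambda = NA, m = NA)
  for (li in seq_len(ncol(coefs))) {
    beta <- coefs[-1, li]
    nz <- which(beta != 0)
    if (length(nz) == 0) next
    ord <- nz[order(-abs(beta[nz]))]
    for (m in top_m_grid) {
      keep <- ord[seq_len(min(m, length(ord)))]
      df <- cbind(1, Ftr[, keep, drop = FALSE])
      ols <- stats::lm.fit(df, train_y)
      b <- ols$coefficients
      b[is.na(b)] <- 0
      pred <- cbind(1, Fva[, keep, drop = FALSE]) %*% b
      mse <- mean((val_y - pred)^2)
      if (mse < best$mse - 1e-12) {
        full <- numeric(length(masks) + 1)
        names(full) <- c("intercept", masks)
        full[1] <- b[1]
        full[1 + keep] <- b[-1]
        best <- list(mse = mse, beta = full,
                     lambda = fit$lambda[li], m = length(keep))
      }
    }
  }
  if (is.null(best$beta)) {
    warning("empty support at every lambda: returning mean-only model")
    best$beta <- c(intercept = mean(train_y),
                   stats::setNames(numeric(length(masks)), masks))
    best$lambda <- max(lambda_grid); best$m <- 0
    best$mse <- mean((val_y - mean(train_y))^2)
  }
  co <- best$beta
  names(co)[1] <- mask_from_sites(integer(0), d)
  co <- co[co != 0]
  model <- if (length(co) > 0) pbf(names(co), unname(co), d) else
    pbf(character(0), numeric(0), d)
  list(model = model,
       report = list(lambda = best$lambda, top_m = best$m,
                     val_mse = best$mse),
       predict = function(X) eval_pbf(model, X))
}

#' Paired synthetic benchmark over methods and seeds
#'
#' For each seed: generate a sparse landscape, sample and split a dataset
#' (identical across methods: paired design), train each requested method,
#' and report test R-squared and spectrum NMSE versus the generating truth.
#'
#' @param d,k_large,k_small,noise_frac landscape parameters; the observation
#'   noise SD is `noise_frac` times the signal SD.
#' @param orders candidate interaction orders for the generated masks.
#' @param n_train,n_val,n_test split sizes.
#' @param methods subset of `"dnn"`, `"dnn+en"`, `"dnn+ens"`, `"lasso"`.
#' @param seeds integer vector of seeds (one paired replicate each).
#' @param f network expansion factor.
#' @param en_epochs,en_patience exact-path training budget.
#' @param ens_outer,ens_epochs ADMM budget.
#' @param ens_C,ens_b plan shape for the ADMM path.
#' @param lasso_max_order feature order for the baseline.
#' @param standardize center/scale responses (train-split statistics) for
#'   the network methods; predictions and spectra are mapped back to the
#'   raw scale before scoring. The spectral penalty weights are calibrated
#'   for responses on a unit scale, so this is on by default.
#' @return data.frame: one row per (seed, method) with r2 and nmse, plus a
#'   `summary` attribute with mean and SEM per method.
#' @export
run_benchmark <- function(d = 13L, k_large = 5L, k_small = 20L,
                          noise_frac = 0.05, orders = 1:5,
                          n_train = 60L, n_val = 60L, n_test = 2000L,
                          methods = c("dnn", "dnn+en"), seeds = 1:10,
                          f = 2L, en_epochs = 800L, en_patience = 150L,
                          ens_outer = 15L, ens_epochs = 30L,
                          ens_C = 3L, ens_b = 6L, lasso_max_order = 2L,
                          standardize = TRUE) {
  rows <- list()
  for (seed in seeds) {
    base_spec <- synthetic_spec(d, k_large, k_small, sigma_e = 0,
                                orders = orders, seed = seed)
    truth <- generate_sparse_landscape(base_spec)$truth
    sigma_e <- noise_frac * landscape_sd(truth)
    land <- generate_sparse_landscape(
      synthetic_spec(d, k_large, k_small, sigma_e = sigma_e,
                     orders = orders, seed = seed))
    n_all <- n_train + n_val + n_test
    X <- sample_dataset(d, n_all, seed = seed)
    y <- land$sampler(X)
    sp <- split_dataset(n_all, n_train, n_val, n_test, seed = seed)
    tr_x <- X[sp$train, , drop = FALSE]; tr_y <- y[sp$train]
    va_x <- X[sp$validation, , drop = FALSE]; va_y <- y[sp$validation]
    te_x <- X[sp$test, , drop = FALSE]; te_y <- y[sp$test]
    truth_spec <- as_spectrum(land$truth)
    mu <- if (standardize) mean(tr_y) else 0
    sc <- if (standardize) stats::sd(tr_y) else 1
    tr_ys <- (tr_y - mu) / sc
    va_ys <- (va_y - mu) / sc
    const_mask <- mask_from_sites(integer(0), d)
    # map a spectrum fitted on the standardized scale back to the raw scale
    unscale_spectrum <- function(est) {
      est <- convert_scale(est, "multilinear")
      est$coefficients <- est$coefficients * sc
      if (const_mask %in% names(est$coefficients)) {
        est$coefficients[[const_mask]] <- est$coefficients[[const_mask]] + mu
      } else if (mu != 0) {
        est$coefficients <- c(stats::setNames(mu, const_mask),
                              est$coefficients)
      }
      est
    }
    for (method in methods) {
      queries <- NA_real_
      if (method == "dnn") {
        fitres <- train_en(build_dnn(d, f, seed), tr_x, tr_ys, va_x, va_ys,
                           en_config(alpha = 0, lr = 0.001,
                                     epochs = en_epochs,
                                     patience = en_patience, seed = seed))
        pred <- predict(fitres$model, te_x) * sc + mu
        est <- unscale_spectrum(spectrum_nonzero(model_spectrum(fitres$model),
                                                 tol = 0))
      } else if (method == "dnn+en") {
        fitres <- train_en(build_dnn(d, f, seed), tr_x, tr_ys, va_x, va_ys,
                           en_config(alpha = 0.1, lr = 0.01,
                                     epochs = en_epochs,
                                     patience = en_patience, seed = seed))
        pred <- predict(fitres$model, te_x) * sc + mu
        est <- unscale_spectrum(spectrum_nonzero(model_spectrum(fitres$model),
                                                 tol = 0))
      } else if (method == "dnn+ens") {
        fitres <- train_ens(build_dnn(d, f, seed), tr_x, tr_ys, va_x, va_ys,
                            ens_config(alpha = 1, rho = 0.01,
                                       outer_iterations = ens_outer,
                                       sgd_epochs = ens_epochs, lr = 0.01,
                                       C = ens_C, b = ens_b,
                                       k_estimate = k_large + k_small,
                                       plan_seed = seed, seed = seed))
        pred <- predict(fitres$model, te_x) * sc + mu
        est <- unscale_spectrum(fitres$u)
        queries <- fitres$queries
      } else if (method == "lasso") {
        fitres <- lasso_wh_baseline(tr_x, tr_y, va_x, va_y,
                                    max_order = lasso_max_order)
        pred <- fitres$predict(te_x)
        est <- as_spectrum(fitres$model)
      } else stop("unknown method: ", method)
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed, method = method,
        r2 = r_squared(te_y, pred),
        nmse = spectrum_nmse(est, truth_spec),
        queries = queries)
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out, out$method), function(g) {
    data.frame(method = g$method[1], n = nrow(g),
               r2_mean = mean(g$r2),
               r2_sem = stats::sd(g$r2) / sqrt(nrow(g)),
               nmse_mean = mean(g$nmse),
               nmse_sem = stats::sd(g$nmse) / sqrt(nrow(g)))
  }))
  attr(out, "summary") <- agg
  out
}
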