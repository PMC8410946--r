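# ADMM spectral training: on-the-fly H_T u, the three steps, order
# histograms, soft-threshold reference.

test_that("ht_times_u matches the dense inverse transform", {
  f <- worked_example_pbf()
  u <- convert_scale(as_spectrum(f), "unitary")
  X <- enumerate_inputs(5)
  expect_equal(ht_times_u(X, u), inverse_wht(u)$values, tolerance = 1e-12)
  # constant-only spectrum and empty spectrum
  uc <- wh_spectrum(stats::setNames(8, mask_from_sites(integer(0), 5)), 5,
                    "unitary")
  expect_equal(ht_times_u(X, uc), rep(8 * 2^(-5 / 2), 32))
  expect_equal(ht_times_u(X, wh_spectrum(numeric(0), 5, "unitary")),
               rep(0, 32))
})

test_that("dual_step is exact residual accumulation", {
  g <- c(1, 2, 3); h <- c(1, 2, 3)
  expect_equal(dual_step(c(5, 5, 5), g, h), c(5, 5, 5))     # zero residual
  expect_equal(dual_step(rep(0, 3), g + 2, h), rep(2, 3))   # constant residual
  g2 <- dual_step(dual_step(rep(0, 3), g + c(1, 0, 1), h), g + c(0, 1, 0), h)
  expect_equal(g2, c(1, 1, 1))                              # additivity
  expect_error(dual_step(1:2, 1:3, 1:3))
})

test_that("u_step recovers a sparse model spectrum and hard-thresholds", {
  d <- 8
  f <- random_sparse_pbf(d, 4, seed = 91)
  plan <- design_plan(d, 4, C = 3, b = 4, seed = 2)
  pts <- sample_points(plan)
  w <- eval_pbf(f, pts$X)                 # gamma = 0, model = exact k-sparse
  st <- u_step(w, pts, plan, alpha = 0, rho = 1)
  expect_setequal(names(st$u$coefficients), f$masks)
  expect_equal(unname(st$u$coefficients[f$masks]) * 2^(-d / 2),
               f$coefficients, tolerance = 1e-9)
  # zero model -> empty u
  st0 <- u_step(numeric(nrow(pts$X)), pts, plan, alpha = 1, rho = 0.01)
  expect_length(st0$u$coefficients, 0)
  # threshold between a large and a small coefficient keeps only the large:
  # unitary u = alpha_S * 2^(d/2); keep iff u^2 >= 2 alpha / rho
  f2 <- pbf(c(mask_from_sites(1, d), mask_from_sites(c(2, 3), d)),
            c(10, 0.002), d)
  w2 <- eval_pbf(f2, pts$X)
  thr_between <- ((0.002 * 2^(d / 2))^2 + (10 * 2^(d / 2))^2) / 2
  st2 <- u_step(w2, pts, plan, alpha = thr_between, rho = 2)
  expect_equal(names(st2$u$coefficients), mask_from_sites(1, d))
})

test_that("theta_step with rho = 0 is plain MSE training and the penalty
           vanishes at its fixed point", {
  d <- 6
  truth <- random_sparse_pbf(d, 2, seed = 95)
  dat <- toy_training_data(d, 30, truth, sigma = 0.2, seed = 12)
  plan <- design_plan(d, 4, C = 2, b = 3, seed = 3)
  pts <- sample_points(plan)
  cfg <- ens_config(sgd_epochs = 5, lr = 0.005, seed = 13)
  u0 <- wh_spectrum(numeric(0), d, "unitary")
  set.seed(13)
  m_rho0 <- theta_step(build_dnn(d, 2, seed = 13), dat$X, dat$y, pts$X,
                       u0, numeric(pts$n_queries), 0, cfg)
  # fixed point: u set to the model's own (full) spectrum, gamma = 0 ->
  # the coupling penalty vanishes at the start of the step
  m <- build_dnn(d, 2, seed = 14)
  g_xt <- predict(m, pts$X)
  u_own <- spectrum_nonzero(model_spectrum(m, "unitary"), tol = 0)
  penalty <- sum((g_xt - ht_times_u(pts$X, u_own))^2)
  expect_lt(penalty, 1e-12 * sum(g_xt^2) + 1e-12)
  expect_true(is.finite(mean((dat$y - predict(m_rho0, dat$X))^2)))
})

test_that("train_ens runs the ADMM loop and zero iterations is data-only", {
  d <- 8
  truth <- random_sparse_pbf(d, 3, seed = 97)
  dat <- toy_training_data(d, 40, truth, sigma = 0.3, seed = 15)
  val <- toy_training_data(d, 20, truth, sigma = 0.3, seed = 16)
  cfg <- ens_config(alpha = 1, rho = 0.01, outer_iterations = 4,
                    sgd_epochs = 10, lr = 0.01, C = 3, b = 4,
                    k_estimate = 5, plan_seed = 17, seed = 17)
  fit <- train_ens(build_dnn(d, 2, seed = 17), dat$X, dat$y, val$X, val$y, cfg)
  expect_equal(nrow(fit$trace), 4)
  expect_length(fit$gamma, fit$queries)
  expect_lte(fit$queries, fit$plan$n_queries)
  expect_length(fit$u_history, 4)
  # diagnostic trend: the primal residual does not blow up over the run
  expect_lte(min(tail(fit$trace$primal_residual, 2)),
             max(head(fit$trace$primal_residual, 2)) * 2)
  # 0 outer iterations: plain MSE-trained model
  cfg0 <- ens_config(outer_iterations = 0, sgd_epochs = 10, lr = 0.01,
                     C = 3, b = 4, k_estimate = 5, plan_seed = 17, seed = 17)
  fit0 <- train_ens(build_dnn(d, 2, seed = 17), dat$X, dat$y, val$X, val$y,
                    cfg0)
  expect_null(fit0$trace)
  expect_true(is.finite(mean((val$y - predict(fit0$model, val$X))^2)))
})

test_that("order_histogram counts interaction orders and adds across entries", {
  empty_mask <- mask_from_sites(integer(0), 5)
  h0 <- order_histogram(list(wh_spectrum(stats::setNames(3, empty_mask), 5,
                                         "unitary")))
  expect_equal(as.integer(h0), 1L)
  expect_equal(names(h0), "0")
  s <- as_spectrum(worked_example_pbf())
  h <- order_histogram(list(s))
  expect_equal(as.integer(h[c("1", "2", "3")]), c(1L, 1L, 1L))
  h2 <- order_histogram(list(s, s))
  expect_equal(as.integer(h2[c("1", "2", "3")]), c(2L, 2L, 2L))
})

test_that("soft_threshold is the l1 prox with threshold alpha/rho", {
  w <- c(-3, -0.5, 0, 0.5, 3)
  expect_equal(soft_threshold(w, alpha = 1, rho = 1),
               c(-2, 0, 0, 0, 2))
  expect_equal(soft_threshold(w, alpha = 0.01, rho = 0.01),
               c(-2, 0, 0, 0, 2))
  expect_equal(soft_threshold(w, alpha = 0, rho = 1), w)
})
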