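# Sparse-graph-code subsampling and the peeling decoder.

test_that("design_plan arithmetic, determinism and rank requirements", {
  p1 <- design_plan(5, 3, C = 2, b = 2, seed = 4)
  expect_equal(p1$n_queries, 2 * 6 * 4)
  p2 <- design_plan(13, 20, C = 3, b = 6, seed = 9)
  expect_equal(p2$n_queries, 3 * 14 * 64)
  expect_identical(design_plan(8, 5, seed = 7), design_plan(8, 5, seed = 7))
  for (M in p2$Ms) expect_equal(gf2_rank(M), 6L)
  expect_warning(design_plan(8, 10, C = 3, b = 3, seed = 1), "unlikely")
  expect_error(design_plan(8, 10, C = 3, b = 3, seed = 1, strict = TRUE))
})

test_that("sample_points produces valid deduplicated queries", {
  plan <- design_plan(5, 3, C = 3, b = 3, seed = 2)
  pts <- sample_points(plan)
  expect_true(all(pts$X %in% c(-1, 1)))
  expect_equal(ncol(pts$X), 5)
  expect_lte(nrow(pts$X), plan$n_queries)
  expect_equal(nrow(unique(pts$X)), nrow(pts$X))
  # zero delay, bin 0 -> the all-reference row
  ref_row <- pts$map[[1]][1, 1]
  expect_equal(pts$X[ref_row, ], rep(1, 5))
  # map indexes every (group, delay, bin) cell
  for (c_i in 1:3) expect_equal(dim(pts$map[[c_i]]), c(6L, 8L))
})

test_that("observations alias single coefficients with delay-sign pattern", {
  d <- 5
  plan <- design_plan(d, 3, C = 3, b = 3, seed = 11)
  pts <- sample_points(plan)
  # single term 12 * x1 x4
  f1 <- pbf(mask_from_sites(c(1, 4), d), 12, d)
  obs <- compute_observations(eval_pbf(f1, pts$X), pts, plan)
  s_bits <- as.integer(strsplit(f1$masks, "")[[1]])
  for (c_i in 1:3) {
    U <- obs$obs[[c_i]]
    j <- plan_hash(plan, c_i, s_bits) + 1
    expect_equal(abs(U[, j]), rep(12, d + 1), tolerance = 1e-9)
    sgn <- 1 - 2 * ((plan$delays %*% s_bits) %% 2)
    expect_equal(U[, j], 12 * as.numeric(sgn), tolerance = 1e-9)
    expect_equal(U[, -j], matrix(0, d + 1, plan$B - 1), tolerance = 1e-9)
  }
  # linearity: two terms hashing to different bins superpose independently
  f2 <- pbf(mask_from_sites(3, d), -3, d)
  obs1 <- compute_observations(eval_pbf(f1, pts$X), pts, plan)
  obs2 <- compute_observations(eval_pbf(f2, pts$X), pts, plan)
  both <- compute_observations(eval_pbf(f1, pts$X) + eval_pbf(f2, pts$X),
                               pts, plan)
  for (c_i in 1:3) {
    expect_equal(both$obs[[c_i]], obs1$obs[[c_i]] + obs2$obs[[c_i]],
                 tolerance = 1e-9)
  }
  # zero values -> zero observations
  zero <- compute_observations(numeric(nrow(pts$X)), pts, plan)
  expect_true(all(unlist(zero$obs) == 0))
})

test_that("detect_bin classifies zero-tons, singletons and collisions", {
  d <- 6
  s_bits <- c(1L, 0L, 0L, 1L, 0L, 0L)
  sgn <- as.numeric(1 - 2 * ((rbind(rep(0L, d), diag(1L, d)) %*% s_bits) %% 2))
  st <- detect_bin(7.5 * sgn, noise_threshold = 1e-6)
  expect_equal(st$type, "singleton")
  expect_equal(st$mask_bits, s_bits)
  expect_equal(st$value, 7.5)
  expect_equal(detect_bin(rep(0, d + 1), 1e-6)$type, "zero-ton")
  # two colliding equal-magnitude coefficients: amplitudes inconsistent
  s2 <- c(0L, 1L, 0L, 0L, 1L, 0L)
  sgn2 <- as.numeric(1 - 2 * ((rbind(rep(0L, d), diag(1L, d)) %*% s2) %% 2))
  expect_equal(detect_bin(5 * sgn + 5 * sgn2, 1e-6)$type, "multi-ton")
})

test_that("peeling recovers the worked example and degenerate cases", {
  f <- worked_example_pbf()
  res <- recover_sparse_wht(function(X) eval_pbf(f, X), d = 5,
                            k_estimate = 3, C = 3, b = 3, seed = 13)
  expect_true(res$converged)
  expect_setequal(names(res$spectrum$coefficients), f$masks)
  expect_equal(unname(res$spectrum$coefficients[f$masks]), f$coefficients,
               tolerance = 1e-9)
  # zero function: empty spectrum, no productive sweeps
  res0 <- recover_sparse_wht(function(X) numeric(nrow(X)), d = 5,
                             k_estimate = 3, C = 3, b = 3, seed = 13)
  expect_length(res0$spectrum$coefficients, 0)
  expect_equal(res0$iterations, 0L)
  # constant oracle: empty-set mask only
  resc <- recover_sparse_wht(function(X) rep(4.5, nrow(X)), d = 6,
                             k_estimate = 2, C = 3, b = 2, seed = 3)
  expect_equal(resc$spectrum$coefficients,
               stats::setNames(4.5, mask_from_sites(integer(0), 6)))
})

test_that("recovery matches dense fwht on random instances", {
  fails <- 0
  for (s in 1:25) {
    d <- 10
    f <- random_sparse_pbf(d, 8, seed = 300 + s)
    res <- recover_sparse_wht(function(X) eval_pbf(f, X), d,
                              k_estimate = 8, C = 3, b = 5, seed = s)
    dense <- spectrum_nonzero(
      fwht(wh_landscape(eval_pbf(f, enumerate_inputs(d)))), tol = 1e-8)
    ok <- setequal(names(res$spectrum$coefficients),
                   names(dense$coefficients)) &&
      max(abs(res$spectrum$coefficients[names(dense$coefficients)] -
                dense$coefficients)) < 1e-6
    fails <- fails + !ok
  }
  expect_lte(fails, 1)
})

test_that("recovery is linear for disjoint non-colliding supports", {
  d <- 9
  f1 <- pbf(c(mask_from_sites(1, d), mask_from_sites(c(2, 3), d)),
            c(5, -7), d)
  f2 <- pbf(c(mask_from_sites(c(4, 5, 6), d), mask_from_sites(9, d)),
            c(3, 11), d)
  r1 <- recover_sparse_wht(function(X) eval_pbf(f1, X), d, 4, b = 4, seed = 8)
  r2 <- recover_sparse_wht(function(X) eval_pbf(f2, X), d, 4, b = 4, seed = 8)
  r12 <- recover_sparse_wht(function(X) eval_pbf(f1, X) + eval_pbf(f2, X),
                            d, 4, b = 4, seed = 8)
  expect_mapequal(as.list(r12$spectrum$coefficients),
                  c(as.list(r1$spectrum$coefficients),
                    as.list(r2$spectrum$coefficients)))
})

test_that("query budget is sublinear and exact at d = 40", {
  d <- 40
  f <- random_sparse_pbf(d, 8, seed = 77)
  calls <- 0L
  oracle <- function(X) { calls <<- calls + nrow(X); eval_pbf(f, X) }
  res <- recover_sparse_wht(oracle, d, k_estimate = 8, C = 3, b = 4, seed = 5)
  expect_equal(res$plan$n_queries, 3 * 41 * 16)
  expect_equal(calls, res$queries)        # oracle touched once per unique row
  expect_lte(res$queries, res$plan$n_queries)
  expect_setequal(names(res$spectrum$coefficients), f$masks)
  expect_equal(unname(res$spectrum$coefficients[f$masks]), f$coefficients,
               tolerance = 1e-9)
})

test_that("plan serialization round trips", {
  plan <- design_plan(13, 10, C = 3, b = 5, seed = 21)
  path <- tempfile(fileext = ".json")
  write_plan_json(plan, path)
  plan2 <- read_plan_json(path)
  expect_equal(plan2$Ms, plan$Ms)
  expect_equal(plan2$n_queries, plan$n_queries)
})
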