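# Encodings, dense transform, pseudo-Boolean evaluation, summaries.

test_that("enumerate_inputs follows the declared convention", {
  expect_equal(enumerate_inputs(1), matrix(c(1, -1), ncol = 1))
  X5 <- enumerate_inputs(5)
  expect_equal(dim(X5), c(32L, 5L))
  expect_equal(nrow(unique(X5)), 32L)
  expect_true(all(X5 %in% c(-1, 1)))
  # exhaustive oracle at d = 8
  expect_equal(enumerate_inputs(8), brute_enumeration(8))
  expect_error(enumerate_inputs(26), "d_max")
})

test_that("fwht recovers the worked example exactly", {
  f <- worked_example_pbf()
  X <- enumerate_inputs(5)
  s <- fwht(wh_landscape(eval_pbf(f, X)), "multilinear")
  nz <- spectrum_nonzero(s)
  expect_length(nz$coefficients, 3)
  expect_equal(nz$coefficients[[mask_from_sites(c(1, 4), 5)]], 12)
  expect_equal(nz$coefficients[[mask_from_sites(3, 5)]], -3)
  expect_equal(nz$coefficients[[mask_from_sites(c(1, 2, 5), 5)]], 6)
})

test_that("fwht equals the Kronecker-built dense transform", {
  for (d in c(3, 6, 8)) {
    set.seed(d)
    v <- stats::rnorm(2^d)
    H <- kron_hadamard(d)
    expect_equal(unname(fwht(wh_landscape(v), "multilinear")$coefficients),
                 as.numeric(H %*% v) / 2^d, tolerance = 1e-11)
    expect_equal(unname(fwht(wh_landscape(v), "unitary")$coefficients),
                 as.numeric(H %*% v) / 2^(d / 2), tolerance = 1e-11)
  }
})

test_that("constant landscapes transform to the empty-set mask only", {
  s <- spectrum_nonzero(fwht(wh_landscape(rep(5, 16)), "multilinear"))
  expect_equal(s$coefficients,
               stats::setNames(5, mask_from_sites(integer(0), 4)))
  expect_equal(inverse_wht(wh_spectrum(stats::setNames(5, "0000"), 4,
                                       "multilinear"))$values,
               rep(5, 16))
})

test_that("transform round trips and scale conversion are exact", {
  set.seed(11)
  for (d in c(4, 10)) {
    v <- stats::rnorm(2^d)
    s <- fwht(wh_landscape(v), "multilinear")
    expect_equal(inverse_wht(s)$values, v, tolerance = 1e-12)
    # unitary <-> multilinear is an exact factor 2^(d/2)
    su <- convert_scale(s, "unitary")
    expect_equal(su$coefficients, s$coefficients * 2^(d / 2))
    expect_equal(convert_scale(su, "multilinear")$coefficients,
                 s$coefficients)
    # sparse spectrum round trip
    f <- random_sparse_pbf(d, 6, seed = d)
    sp <- as_spectrum(f)
    expect_equal(fwht(inverse_wht(sp))$coefficients[names(sp$coefficients)],
                 sp$coefficients, tolerance = 1e-12)
  }
  expect_error(fwht(wh_landscape(rnorm(12))), "2\\^d")
})

test_that("Parseval and unnormalized involution hold", {
  set.seed(21)
  for (d in c(5, 9, 12)) {
    v <- stats::rnorm(2^d)
    u <- fwht(wh_landscape(v), "unitary")$coefficients
    expect_equal(sum(u^2), sum(v^2), tolerance = 1e-9)
    expect_equal(fwht_core(fwht_core(v)), 2^d * v, tolerance = 1e-9)
  }
})

test_that("eval_pbf matches direct substitution", {
  f <- worked_example_pbf()
  expect_equal(eval_pbf(f, rep(1, 5)), 12 - 3 + 6)
  expect_equal(eval_pbf(f, c(-1, 1, 1, -1, 1)), 12 - 3 - 6)
  expect_equal(eval_pbf(pbf(character(0), numeric(0), 4),
                        enumerate_inputs(4)),
               rep(0, 16))
  expect_error(eval_pbf(f, matrix(1, 2, 4)), "width")
})

test_that("transform of evaluations uniquely recovers generating terms", {
  for (s in 1:100) {
    d <- sample(4:10, 1)
    f <- random_sparse_pbf(d, sample(1:8, 1), seed = s)
    sp <- spectrum_nonzero(fwht(wh_landscape(eval_pbf(f, enumerate_inputs(d)))),
                           tol = 1e-8)
    expect_setequal(names(sp$coefficients), f$masks)
    expect_equal(unname(sp$coefficients[f$masks]), f$coefficients,
                 tolerance = 1e-9)
  }
})

test_that("variance_explained_curve is correct, monotone, tie-stable", {
  f <- worked_example_pbf()
  s <- fwht(wh_landscape(eval_pbf(f, enumerate_inputs(5))))
  ve <- variance_explained_curve(s, 3)
  expect_equal(ve[1], 144 / 189, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ve[3], 1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(diff(ve) >= 0))
  # single non-constant coefficient; constant term excluded
  s1 <- wh_spectrum(c("000" = 7, "100" = 2), 3, "multilinear")
  expect_equal(variance_explained_curve(s1, 1), 1, ignore_attr = TRUE)
  # two equal magnitudes -> 0.5 then 1
  s2 <- wh_spectrum(c("10" = 3, "01" = -3), 2, "multilinear")
  expect_equal(variance_explained_curve(s2), c(0.5, 1), ignore_attr = TRUE)
  expect_error(variance_explained_curve(
    wh_spectrum(c("00" = 4), 2, "multilinear")), "degenerate")
})

test_that("encodings are injective and invertible", {
  enc13 <- site_encoding("binary-site", 13)
  expect_equal(enc13$d, 13L)
  set.seed(5)
  seqs <- vapply(1:20, function(i) {
    paste(sample(c("0", "1"), 13, TRUE), collapse = "")
  }, character(1))
  X <- encode_sequences(seqs, enc13)
  expect_true(all(X %in% c(-1, 1)))
  expect_equal(decode_sequences(X, enc13), seqs)
  # reference state is +1
  expect_equal(encode_sequences("0000000000000", enc13)[1, ], rep(1, 13))

  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  enc <- site_encoding("one-hot-block", 4, alphabet = aa)
  expect_equal(enc$d, 80L)
  seqs <- c("ACDE", "YYYY", "KLMN")
  X <- encode_sequences(seqs, enc)
  # exactly one designated-state bit per site
  expect_true(all(apply(X, 1, function(r) sum(r < 0)) == 4))
  expect_equal(decode_sequences(X, enc), seqs)
  expect_error(encode_sequences("ACDZ", enc), "unknown symbol")
  expect_error(encode_sequences("ACD", enc), "length")
})

test_that("spectrum and landscape serialization round trips", {
  f <- worked_example_pbf()
  s <- as_spectrum(f)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_spectrum_tsv(s, tsv)
  expect_equal(read_spectrum_tsv(tsv)$coefficients, s$coefficients)
  write_spectrum_json(s, js)
  expect_equal(read_spectrum_json(js)$coefficients, s$coefficients)
  L <- inverse_wht(s)
  csv <- tempfile(fileext = ".csv")
  write_landscape_csv(L, csv)
  expect_equal(read_landscape_csv(csv)$values, L$values)
})
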