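# Synthetic sparse-epistasis landscapes: a few large-magnitude interaction
# coefficients plus a larger band of small ones, observed with additive
# zero-mean Gaussian noise. Plus dataset sampling/splitting and the Box-Cox
# preprocessing stage.

#' Specification of a synthetic sparse landscape
#'
#' The stated world: `k_large` interactions with coefficients drawn
#' uniformly from +/-[8, 16] and `k_small` with +/-[0.1, 1]; mask orders
#' uniform over 1..5 (capped at d), then uniform over masks of that order;
#' observations carry N(0, sigma_e^2) noise (the stored ground truth never
#' does).
#'
#' @param d number of sites.
#' @param k_large,k_small counts of large/small-magnitude terms.
#' @param sigma_e observation noise standard deviation (>= 0).
#' @param orders candidate interaction orders for the masks.
#' @param large_range,small_range absolute-magnitude ranges.
#' @param seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(d, k_large = 5L, k_small = 20L, sigma_e = 0,
                           orders = 1:5, large_range = c(8, 16),
                           small_range = c(0.1, 1), seed = 1L) {
  stopifnot(d >= 1, k_large >= 0, k_small >= 0, sigma_e >= 0)
  orders <- orders[orders <= d & orders >= 1]
  stopifnot(length(orders) > 0)
  n_masks <- sum(choose(d, orders))
  if (k_large + k_small > n_masks) {
    stop("infeasible: ", k_large + k_small, " masks requested but only ",
         n_masks, " exist at the allowed orders")
  }
  structure(list(d = as.integer(d), k_large = as.integer(k_large),
                 k_small = as.integer(k_small), sigma_e = sigma_e,
                 orders = as.integer(orders), large_range = large_range,
                 small_range = small_range, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a sparse epistatic landscape
#'
#' @param spec a [synthetic_spec()].
#' @return list with `truth` (a `pbf`, reproducible from the seed) and
#'   `sampler(X)`, which returns noisy observations
#'   `eval_pbf(truth, X) + N(0, sigma_e^2)` with its own reproducible noise
#'   stream (independent of the ambient RNG state).
#' @export
generate_sparse_landscape <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(spec$seed)
  k <- spec$k_large + spec$k_small
  masks <- character(0)
  while (length(masks) < k) {
    o <- sample(rep(spec$orders, 2), 1)   # rep() guards length-1 sample()
    masks <- unique(c(masks, mask_from_sites(sample.int(spec$d, o), spec$d)))
  }
  masks <- masks[seq_len(k)]
  mag <- c(stats::runif(spec$k_large, spec$large_range[1], spec$large_range[2]),
           stats::runif(spec$k_small, spec$small_range[1], spec$small_range[2]))
  sgn <- sample(c(-1, 1), k, replace = TRUE)
  truth <- pbf(masks, mag * sgn, spec$d)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  counter <- new.env(parent = emptyenv())
  counter$calls <- 0L
  sampler <- function(X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    y <- eval_pbf(truth, X)
    if (spec$sigma_e > 0) {
      counter$calls <- counter$calls + 1L
      saved <- get0(".Random.seed", envir = globalenv())
      set.seed((spec$seed + 104729 * counter$calls) %% 2147483647)
      y <- y + stats::rnorm(length(y), 0, spec$sigma_e)
      if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
    }
    y
  }
  list(truth = truth, sampler = sampler, spec = spec)
}

#' Standard deviation of a sparse landscape over the uniform hypercube
#'
#' By Parseval, the variance of f over uniform +/-1 inputs is the sum of
#' squared non-constant multilinear coefficients.
#'
#' @param truth a `pbf`.
#' @return the signal standard deviation.
#' @export
landscape_sd <- function(truth) {
  stopifnot(inherits(truth, "pbf"))
  nonconst <- truth$coefficients[mask_order(truth$masks) > 0]
  sqrt(sum(nonconst^2))
}

#' Sample sequences uniformly without replacement from the input space
#'
#' @param d number of sites.
#' @param n number of samples (n <= 2^d).
#' @param seed RNG seed.
#' @return an n x d +/-1 matrix of distinct rows.
#' @export
sample_dataset <- function(d, n, seed = 1L) {
  if (d <= 30 && n > 2^d) stop("n = ", n, " exceeds 2^d")
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  if (d <= 25) {
    j <- sample.int(2^d, n) - 1
    X <- vapply(seq_len(d), function(i) 1 - 2 * ((j %/% 2^(i - 1)) %% 2),
                numeric(n))
    X <- matrix(X, nrow = n)
  } else {
    # collision probability is negligible at this scale; dedup regardless
    X <- NULL
    while (is.null(X) || nrow(X) < n) {
      draw <- matrix(sample(c(-1, 1), 2 * n * d, replace = TRUE), ncol = d)
      X <- unique(rbind(X, draw))
    }
    X <- X[seq_len(n), , drop = FALSE]
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  storage.mode(X) <- "double"
  X
}

#' Split sample indices into train / validation / test sets
#'
#' @param n_samples total number of available samples.
#' @param train_n,val_n,test_n disjoint set sizes
#'   (sum <= `n_samples`).
#' @param seed RNG seed.
#' @return list of disjoint integer index vectors `train`, `validation`,
#'   `test`.
#' @export
split_dataset <- function(n_samples, train_n, val_n, test_n, seed = 1L) {
  if (train_n + val_n + test_n > n_samples) {
    stop("infeasible split: ", train_n + val_n + test_n, " > ", n_samples)
  }
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  perm <- sample.int(n_samples)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(train = perm[seq_len(train_n)],
       validation = perm[train_n + seq_len(val_n)],
       test = perm[train_n + val_n + seq_len(test_n)])
}

#' Box-Cox preprocessing of fitness values
#'
#' Chooses the power by profile log-likelihood over a fixed 101-point grid
#' on [-2, 2]; nonpositive values are min-shifted to positivity (plus a
#' small epsilon) unless `strict`, in which case they are rejected. The
#' transform is monotone; an exact inverse is returned.
#'
#' @param y numeric fitness values.
#' @param strict refuse nonpositive values instead of shifting.
#' @param grid candidate powers.
#' @return list: `values` (transformed), `lambda`, `shift`, `transform(y)`
#'   and `inverse(z)` functions.
#' @export
boxcox_preprocess <- function(y, strict = FALSE,
                              grid = seq(-2, 2, length.out = 101)) {
  stopifnot(all(is.finite(y)), length(y) >= 2)
  if (stats::sd(y) == 0) stop("degenerate input: constant fitness vector")
  shift <- 0
  if (min(y) <= 0) {
    if (strict) stop("nonpositive values not allowed in strict mode")
    shift <- -min(y) + 1e-3 * diff(range(y))
  }
  yp <- y + shift
  n <- length(yp)
  slog <- sum(log(yp))
  ll <- vapply(grid, function(l) {
    z <- if (abs(l) < 1e-12) log(yp) else (yp^l - 1) / l
    -n / 2 * log(mean((z - mean(z))^2)) + (l - 1) * slog
  }, numeric(1))
  lambda <- grid[which.max(ll)]
  transform <- function(v) {
    vp <- v + shift
    if (abs(lambda) < 1e-12) log(vp) else (vp^lambda - 1) / lambda
  }
  inverse <- function(z) {
    vp <- if (abs(lambda) < 1e-12) exp(z) else (lambda * z + 1)^(1 / lambda)
    vp - shift
  }
  list(values = transform(y), lambda = lambda, shift = shift,
       transform = transform, inverse = inverse)
}
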