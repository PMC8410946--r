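# Sublinear sparse Walsh-Hadamard recovery via sparse-graph codes.
#
# A plan hashes each of the 2^d coefficients into B = 2^b bins per group
# through a random full-column-rank (over GF(2)) map M_c; querying the
# function on the coset {M_c l xor delta} and taking a small (length-B)
# WH transform aliases coefficient alpha_S into bin M_c' S with sign
# (-1)^<S, delta>. With d+1 delays (zero offset plus the unit vectors e_i)
# a bin holding a single coefficient reveals its mask through sign flips and
# its value through the common amplitude; peeling subtracts found
# coefficients everywhere and repeats.

# rank over GF(2); used to reject degenerate subsampling maps
gf2_rank <- function(M) {
  M <- M %% 2L
  r <- 0L
  for (col in seq_len(ncol(M))) {
    piv <- which(M[, col] == 1L)
    piv <- piv[piv > r]
    if (length(piv) == 0) next
    r <- r + 1L
    if (piv[1] != r) M[c(r, piv[1]), ] <- M[c(piv[1], r), ]
    other <- setdiff(which(M[, col] == 1L), r)
    if (length(other) > 0) {
      M[other, ] <- (M[other, , drop = FALSE] +
                       matrix(M[r, ], nrow = length(other),
                              ncol = ncol(M), byrow = TRUE)) %% 2L
    }
  }
  r
}

#' Design a sparse-graph-code sampling plan
#'
#' @param d number of sites.
#' @param k_estimate anticipated spectral sparsity; bins should satisfy
#'   2^b >= 2 * k_estimate for high-probability peeling.
#' @param C number of independent hash groups (>= 2).
#' @param b bin bits per group (B = 2^b bins); default `ceiling(log2(k)) + 1`.
#' @param seed RNG seed; identical seeds give identical plans.
#' @param strict if `TRUE`, refuse when 2^b <= k_estimate instead of warning.
#' @return a `sampling_plan`: subsampling maps `Ms` (d x b binary, full
#'   column rank over GF(2)), the d+1 delay offsets (zero first, then unit
#'   vectors), and the query budget `n_queries = C * (d+1) * 2^b`.
#' @export
design_plan <- function(d, k_estimate, C = 3L, b = NULL, seed = 1L,
                        strict = FALSE) {
  stopifnot(d >= 1, C >= 2, k_estimate >= 1)
  if (is.null(b)) b <- max(1L, as.integer(ceiling(log2(k_estimate)) + 1))
  b <- as.integer(min(b, d))
  if (2^b <= k_estimate) {
    msg <- sprintf("2^b = %d bins <= k_estimate = %d: peeling unlikely to converge",
                   2^b, k_estimate)
    if (strict) stop(msg) else warning(msg)
  }
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  Ms <- vector("list", C)
  for (c_i in seq_len(C)) {
    repeat {
      M <- matrix(sample(0:1, d * b, replace = TRUE), nrow = d, ncol = b)
      if (gf2_rank(M) == b) break
    }
    Ms[[c_i]] <- M
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  delays <- rbind(rep.int(0L, d), diag(1L, d))
  structure(list(d = as.integer(d), C = as.integer(C), b = b, B = 2L^b,
                 Ms = Ms, delays = delays, seed = as.integer(seed),
                 k_estimate = as.integer(k_estimate),
                 n_queries = C * (d + 1) * 2^b),
            class = "sampling_plan")
}

# hash of a mask-bit vector s under group c: little-endian bin index M_c' s
plan_hash <- function(plan, c_i, s_bits) {
  h <- (as.integer(crossprod(plan$Ms[[c_i]], s_bits))) %% 2L
  sum(h * 2^(seq_len(plan$b) - 1))
}

# bin-index bit matrix: row j+1 = little-endian bits of j, B x b
bin_bits <- function(b) {
  j <- 0:(2^b - 1)
  vapply(seq_len(b), function(i) (j %/% 2^(i - 1)) %% 2, numeric(2^b))
}

#' Materialize the query points of a plan
#'
#' The query index vector for group c, bin l, delay delta is
#' `M_c l xor delta`; duplicates across the plan are removed, keeping an
#' index map so bin observations can be reassembled.
#'
#' @param plan a `sampling_plan`.
#' @return list with `X` (unique +/-1 query matrix, the canonical bit->sign
#'   convention: bit 0 -> +1), `n_queries` (nrow of X, after dedup) and
#'   `map[[c]]`: a (d+1) x B integer matrix of row indices into X.
#' @export
sample_points <- function(plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  d <- plan$d; B <- plan$B
  L <- bin_bits(plan$b)                       # B x b
  all_bits <- vector("list", plan$C)
  for (c_i in seq_len(plan$C)) {
    base <- (L %*% t(plan$Ms[[c_i]])) %% 2    # B x d: M_c l
    per_delay <- lapply(seq_len(d + 1), function(di) {
      (base + matrix(plan$delays[di, ], nrow = B, ncol = d,
                     byrow = TRUE)) %% 2
    })
    all_bits[[c_i]] <- do.call(rbind, per_delay) # (d+1)*B x d
  }
  bits <- do.call(rbind, all_bits)
  keys <- bits_to_masks(bits)
  ukeys <- unique(keys)
  row_of <- match(keys, ukeys)
  ubits <- bits[match(ukeys, keys), , drop = FALSE]
  X <- 1 - 2 * ubits
  storage.mode(X) <- "double"
  map <- vector("list", plan$C)
  off <- 0L
  for (c_i in seq_len(plan$C)) {
    map[[c_i]] <- matrix(row_of[off + seq_len((d + 1) * B)],
                         nrow = d + 1, ncol = B, byrow = TRUE)
    off <- off + (d + 1L) * B
  }
  list(X = X, n_queries = nrow(X), map = map)
}

#' Compute bin observations from query values
#'
#' For each group and delay, the length-B vector of bin observations is the
#' small WH transform (normalized by 1/B) of the queried values, so a lone
#' coefficient alpha_S shows up in bin `hash(S)` with amplitude alpha_S and
#' delay-sign pattern (-1)^<S, delta>.
#'
#' @param values numeric vector aligned with `points$X` rows.
#' @param points output of [sample_points()].
#' @param plan the `sampling_plan`.
#' @return an `observation_set`: `obs[[c]]` is a (d+1) x B matrix (delay 0
#'   in row 1), plus a median-based noise-scale estimate.
#' @export
compute_observations <- function(values, points, plan) {
  stopifnot(length(values) == nrow(points$X))
  if (!all(is.finite(values))) stop("non-finite query values")
  obs <- vector("list", plan$C)
  for (c_i in seq_len(plan$C)) {
    U <- matrix(0, nrow = plan$d + 1, ncol = plan$B)
    for (di in seq_len(plan$d + 1)) {
      U[di, ] <- fwht_core(values[points$map[[c_i]][di, ]]) / plan$B
    }
    obs[[c_i]] <- U
  }
  allU <- abs(unlist(obs))
  noise_scale <- 1.4826 * stats::median(allU)
  structure(list(obs = obs, noise_scale = noise_scale, plan_d = plan$d,
                 B = plan$B), class = "observation_set")
}

#' Classify a single bin from its d+1 delayed observations
#'
#' Zero-ton if the bin energy is at or below the squared noise scale;
#' otherwise a singleton candidate is read off the sign pattern across the
#' unit delays (mask bit i = 1 iff the sign flips under delay e_i) and
#' accepted when the sign-aligned observations agree with a single common
#' amplitude up to the noise scale (variance test: their spread must not
#' exceed the larger of the squared noise scale and (0.35 value)^2);
#' multi-ton otherwise. Ambiguity always resolves to multi-ton; in the
#' peeling decoder a candidate must additionally re-hash to the bin it was
#' found in. The noise scale makes the test adaptive: with exact data it
#' collapses to an exact test, over a dense background (e.g. the spectrum
#' of a trained network, which is never exactly sparse) it tolerates the
#' aliased residual.
#'
#' @param v numeric vector of d+1 observations (zero delay first).
#' @param noise_threshold noise (rms) scale separating signal from
#'   background.
#' @return list with `type` ("zero-ton", "singleton", "multi-ton"), and for
#'   singletons `mask_bits` (0/1 vector of length d) and `value`.
#' @export
detect_bin <- function(v, noise_threshold) {
  energy <- mean(v^2)
  if (energy <= noise_threshold^2) {
    return(list(type = "zero-ton", energy = energy))
  }
  if (v[1] == 0) return(list(type = "multi-ton", energy = energy))
  s_bits <- as.integer(v[1] * v[-1] < 0)
  aligned <- c(v[1], v[-1] * (1 - 2 * s_bits))
  value <- mean(aligned)
  if (abs(value) <= noise_threshold) {
    return(list(type = "multi-ton", energy = energy))
  }
  spread <- mean((aligned - value)^2)
  if (spread > max((0.35 * value)^2, noise_threshold^2)) {
    return(list(type = "multi-ton", energy = energy))
  }
  list(type = "singleton", mask_bits = s_bits, value = value, energy = energy)
}

#' Peeling decoder over the sparse-graph code
#'
#' Sweeps the bins, extracts singletons, subtracts each recovered
#' coefficient's contribution from every group (re-hashing per group), and
#' repeats until no singleton remains or `max_iterations` sweeps elapse.
#'
#' @param observations an `observation_set`.
#' @param plan the matching `sampling_plan`.
#' @param max_iterations maximum productive sweeps; default
#'   `2 * k_estimate + 10`.
#' @param noise_threshold detection threshold; default
#'   `max(3 * noise_scale, 1e-9 * (max|U| + 1))`.
#' @return a `recovery_result`: the sparse multilinear `spectrum`,
#'   `iterations` (productive sweeps), `residual_energy`,
#'   `unresolved_bins` and `converged`.
#' @export
peel <- function(observations, plan, max_iterations = NULL,
                 noise_threshold = NULL) {
  stopifnot(inherits(observations, "observation_set"),
            observations$plan_d == plan$d, observations$B == plan$B)
  obs <- observations$obs
  d <- plan$d; B <- plan$B
  if (is.null(max_iterations)) max_iterations <- 2L * plan$k_estimate + 10L
  if (is.null(noise_threshold)) {
    umax <- max(abs(unlist(obs)), 0)
    noise_threshold <- max(2 * observations$noise_scale, 1e-9 * (umax + 1))
  }
  recovered <- new.env(parent = emptyenv())
  iterations <- 0L
  repeat {
    found <- FALSE
    for (c_i in seq_len(plan$C)) {
      for (j in seq_len(B)) {
        st <- detect_bin(obs[[c_i]][, j], noise_threshold)
        if (st$type != "singleton") next
        # a genuine singleton must hash to the bin it was found in
        if (plan_hash(plan, c_i, st$mask_bits) != j - 1) next
        key <- paste(st$mask_bits, collapse = "")
        prev <- get0(key, envir = recovered, ifnotfound = 0)
        assign(key, prev + st$value, envir = recovered)
        # subtract the contribution from every group
        sgn <- 1 - 2 * ((plan$delays %*% st$mask_bits) %% 2)
        for (c2 in seq_len(plan$C)) {
          j2 <- plan_hash(plan, c2, st$mask_bits) + 1
          obs[[c2]][, j2] <- obs[[c2]][, j2] - st$value * sgn
        }
        found <- TRUE
      }
    }
    if (found) iterations <- iterations + 1L
    if (!found || iterations >= max_iterations) break
  }
  energies <- lapply(obs, function(U) colMeans(U^2))
  unresolved <- sum(unlist(energies) > noise_threshold^2)
  masks <- ls(recovered)
  vals <- vapply(masks, get, numeric(1), envir = recovered)
  keep <- abs(vals) > noise_threshold
  co <- vals[keep]
  names(co) <- masks[keep]
  structure(list(spectrum = wh_spectrum(co, d, "multilinear"),
                 iterations = iterations,
                 residual_energy = sum(unlist(energies)),
                 unresolved_bins = unresolved,
                 converged = unresolved == 0L,
                 noise_threshold = noise_threshold),
            class = "recovery_result")
}

#' Recover a sparse WH spectrum from a black-box function
#'
#' Composes [design_plan()], [sample_points()], the oracle,
#' [compute_observations()] and [peel()]. The oracle is queried exactly once
#' per unique plan row; nothing of size 2^d is ever allocated.
#'
#' @param oracle function taking an n x d +/-1 matrix, returning n values.
#' @param d number of sites.
#' @param k_estimate anticipated sparsity.
#' @param C,b,seed plan parameters (see [design_plan()]).
#' @param noise_threshold,max_iterations forwarded to [peel()].
#' @return a `recovery_result` with the additional fields `queries` (number
#'   of unique oracle evaluations) and `plan`.
#' @export
recover_sparse_wht <- function(oracle, d, k_estimate, C = 3L, b = NULL,
                               seed = 1L, noise_threshold = NULL,
                               max_iterations = NULL) {
  plan <- design_plan(d, k_estimate, C = C, b = b, seed = seed)
  pts <- sample_points(plan)
  values <- oracle(pts$X)
  stopifnot(length(values) == nrow(pts$X))
  res <- peel(compute_observations(values, pts, plan), plan,
              max_iterations = max_iterations,
              noise_threshold = noise_threshold)
  res$queries <- pts$n_queries
  res$plan <- plan
  res
}

#' Serialize / load a sampling plan as JSON
#'
#' @param plan a `sampling_plan`.
#' @param path file path.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "sampling_plan"))
  obj <- list(d = plan$d, C = plan$C, b = plan$b, seed = plan$seed,
              k_estimate = plan$k_estimate,
              maps = lapply(plan$Ms, function(M) {
                apply(M, 2, paste, collapse = "")
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- design_plan(obj$d, obj$k_estimate, C = obj$C, b = obj$b,
                      seed = obj$seed)
  # rebuild the maps verbatim (defensive: seed already reproduces them);
  # jsonlite simplifies equal-length column lists to a C x b matrix
  maps <- if (is.matrix(obj$maps)) {
    lapply(seq_len(nrow(obj$maps)), function(i) obj$maps[i, ])
  } else obj$maps
  plan$Ms <- lapply(maps, function(cols) {
    M <- vapply(cols, function(s) as.integer(strsplit(s, "")[[1]]),
                integer(obj$d))
    matrix(M, nrow = obj$d)
  })
  plan
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(paste0("sparse WH recovery: %d coefficients, %d sweeps, ",
                     "converged = %s, unresolved bins = %d\n"),
              length(x$spectrum$coefficients), x$iterations,
              x$converged, x$unresolved_bins))
  invisible(x)
}
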