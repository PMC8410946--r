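# Dense Walsh-Hadamard machinery: landscapes, spectra, the fast transform,
# pseudo-Boolean evaluation and variance-explained summaries.
#
# Conventions (fixed once, used everywhere):
#   * enumeration: landscape entry j (0-based) is the value at the +/-1
#     vector whose i-th coordinate is +1 iff bit i-1 of j is 0;
#   * index<->subset bijection: bit i-1 of an index corresponds to site i;
#   * multilinear scale: coefficients are the alpha_S of the polynomial
#     f(x) = sum_S alpha_S prod_{i in S} x_i, i.e. H f / 2^d;
#   * unitary scale: multilinear * 2^(d/2), so that the transform is
#     norm-preserving ((1/2^d) H H = I).

MAX_DENSE_D <- 25L

#' Construct a full fitness landscape
#'
#' A landscape is the vector of a function's values on all 2^d binary inputs
#' in the canonical enumeration order.
#'
#' @param values numeric vector of length 2^d, all finite.
#' @param d number of binary sites; inferred from `length(values)` if missing.
#' @return an object of class `wh_landscape`.
#' @export
wh_landscape <- function(values, d = NULL) {
  if (is.null(d)) {
    d <- as.integer(round(log2(length(values))))
  }
  if (length(values) != 2^d) {
    stop("malformed landscape: length must be 2^d (got ", length(values),
         " for d = ", d, ")")
  }
  if (!all(is.finite(values))) stop("malformed landscape: non-finite values")
  structure(list(d = as.integer(d), values = as.numeric(values)),
            class = "wh_landscape")
}

#' Construct a Walsh-Hadamard spectrum
#'
#' @param coefficients named numeric vector; names are length-d subset
#'   bitstrings (see [mask_from_sites()]).
#' @param d number of sites.
#' @param scale `"multilinear"` (polynomial coefficients alpha_S) or
#'   `"unitary"` (norm-preserving, multilinear * 2^(d/2)).
#' @return an object of class `wh_spectrum`.
#' @export
wh_spectrum <- function(coefficients, d, scale = c("multilinear", "unitary")) {
  scale <- match.arg(scale)
  nm <- names(coefficients)
  if (length(coefficients) > 0) {
    if (is.null(nm) || any(nchar(nm) != d) || anyDuplicated(nm)) {
      stop("spectrum coefficients must have unique length-d bitstring names")
    }
  }
  structure(list(d = as.integer(d), coefficients = coefficients, scale = scale),
            class = "wh_spectrum")
}

#' Convert a spectrum between the multilinear and unitary scales
#'
#' The conversion is exact: unitary = multilinear * 2^(d/2).
#'
#' @param spectrum a `wh_spectrum`.
#' @param scale target scale.
#' @return the spectrum on the requested scale.
#' @export
convert_scale <- function(spectrum, scale = c("multilinear", "unitary")) {
  scale <- match.arg(scale)
  if (spectrum$scale == scale) return(spectrum)
  fac <- if (scale == "unitary") 2^(spectrum$d / 2) else 2^(-spectrum$d / 2)
  wh_spectrum(spectrum$coefficients * fac, spectrum$d, scale)
}

#' Drop numerically-zero coefficients from a spectrum
#'
#' @param spectrum a `wh_spectrum`.
#' @param tol magnitudes at or below `tol` are dropped.
#' @return a sparse `wh_spectrum` on the same scale.
#' @export
spectrum_nonzero <- function(spectrum, tol = 1e-9) {
  keep <- abs(spectrum$coefficients) > tol
  wh_spectrum(spectrum$coefficients[keep], spectrum$d, spectrum$scale)
}

#' Construct a sparse pseudo-Boolean function
#'
#' The multilinear representation f(x) = sum_S alpha_S prod_{i in S} x_i over
#' x in {-1,+1}^d; terms are (subset mask, coefficient) pairs.
#'
#' @param masks character vector of length-d bitstrings, unique.
#' @param coefficients numeric vector, same length, all nonzero.
#' @param d number of sites.
#' @return an object of class `pbf`.
#' @export
pbf <- function(masks, coefficients, d) {
  stopifnot(length(masks) == length(coefficients))
  if (anyDuplicated(masks)) stop("pbf masks must be unique")
  if (length(masks) > 0 && any(nchar(masks) != d)) {
    stop("pbf masks must have length d")
  }
  if (any(coefficients == 0)) stop("pbf coefficients must be nonzero")
  structure(list(d = as.integer(d), masks = masks,
                 coefficients = as.numeric(coefficients)), class = "pbf")
}

#' Convert a sparse pseudo-Boolean function to a spectrum (and back)
#'
#' @param x a `pbf` or a `wh_spectrum`.
#' @return the other representation (pbf terms are multilinear coefficients).
#' @export
as_spectrum <- function(x) {
  stopifnot(inherits(x, "pbf"))
  co <- x$coefficients
  names(co) <- x$masks
  wh_spectrum(co, x$d, "multilinear")
}

#' @rdname as_spectrum
#' @export
as_pbf <- function(x) {
  stopifnot(inherits(x, "wh_spectrum"))
  s <- spectrum_nonzero(convert_scale(x, "multilinear"), tol = 0)
  pbf(names(s$coefficients), unname(s$coefficients), s$d)
}

#' Enumerate all binary inputs of width d
#'
#' Row j (1-based row j corresponds to index j-1) follows the canonical
#' enumeration: coordinate i is +1 iff bit i-1 of the index is 0.
#'
#' @param d number of sites, at most `d_max`.
#' @param d_max refusal boundary; enumeration is exponential in d, and beyond
#'   this the subsampled sparse-transform pathway should be used instead.
#' @return a 2^d x d matrix with entries in {-1, +1}.
#' @export
enumerate_inputs <- function(d, d_max = MAX_DENSE_D) {
  stopifnot(d >= 1)
  if (d > d_max) {
    stop("d = ", d, " exceeds d_max = ", d_max,
         ": full enumeration is infeasible; use the sparse pathway ",
         "(recover_sparse_wht / train_ens)")
  }
  j <- 0:(2^d - 1)
  X <- vapply(seq_len(d),
              function(i) 1 - 2 * ((j %/% 2^(i - 1)) %% 2),
              numeric(2^d))
  matrix(X, nrow = 2^d, ncol = d)
}

# Unnormalized in-place radix-2 butterfly; returns H %*% v for the Sylvester
# ordering H[j,m] = (-1)^popcount(j & m). O(p log p).
fwht_core <- function(v) {
  n <- length(v)
  h <- 1L
  while (h < n) {
    m <- matrix(v, nrow = 2L * h)
    top <- m[seq_len(h), , drop = FALSE]
    bot <- m[h + seq_len(h), , drop = FALSE]
    v <- as.numeric(rbind(top + bot, top - bot))
    h <- 2L * h
  }
  v
}

#' Fast Walsh-Hadamard transform of a full landscape
#'
#' O(p log p) butterfly implementation of multiplication by the Hadamard
#' matrix H (Sylvester recursion), normalized to the requested scale.
#'
#' @param landscape a `wh_landscape` (or a bare numeric vector of length 2^d).
#' @param scale output scale, `"multilinear"` or `"unitary"`.
#' @return a dense `wh_spectrum`.
#' @export
fwht <- function(landscape, scale = c("multilinear", "unitary")) {
  scale <- match.arg(scale)
  if (!inherits(landscape, "wh_landscape")) landscape <- wh_landscape(landscape)
  d <- landscape$d
  raw <- fwht_core(landscape$values)
  co <- if (scale == "multilinear") raw / 2^d else raw / 2^(d / 2)
  names(co) <- all_masks(d)
  wh_spectrum(co, d, scale)
}

#' Inverse Walsh-Hadamard transform
#'
#' Maps a (possibly sparse) spectrum back to the full landscape; exact
#' round-trip with [fwht()] up to floating point.
#'
#' @param spectrum a `wh_spectrum`.
#' @return a `wh_landscape`.
#' @export
inverse_wht <- function(spectrum) {
  stopifnot(inherits(spectrum, "wh_spectrum"))
  if (!spectrum$scale %in% c("multilinear", "unitary")) {
    stop("unknown spectrum scale: ", spectrum$scale)
  }
  d <- spectrum$d
  s <- convert_scale(spectrum, "multilinear")
  dense <- numeric(2^d)
  if (length(s$coefficients) > 0) {
    dense[mask_index(names(s$coefficients)) + 1] <- s$coefficients
  }
  # f = H alpha for the symmetric H; butterfly again, no normalization
  wh_landscape(fwht_core(dense), d)
}

#' Evaluate a sparse pseudo-Boolean function on +/-1 inputs
#'
#' @param fn a `pbf`.
#' @param inputs n x d matrix with entries in {-1, +1} (a single vector is
#'   treated as one row).
#' @return numeric vector of n values sum_S alpha_S prod_{i in S} x_i.
#' @export
eval_pbf <- function(fn, inputs) {
  stopifnot(inherits(fn, "pbf"))
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1)
  if (ncol(inputs) != fn$d) {
    stop("input width ", ncol(inputs), " does not match d = ", fn$d)
  }
  y <- numeric(nrow(inputs))
  if (length(fn$masks) == 0) return(y)
  neg <- inputs < 0
  for (t in seq_along(fn$masks)) {
    sites <- sites_from_mask(fn$masks[t])
    if (length(sites) > 0 && max(sites) > fn$d) {
      stop("mask references site beyond d")
    }
    sign <- if (length(sites) == 0) {
      rep.int(1, nrow(inputs))
    } else {
      1 - 2 * (rowSums(neg[, sites, drop = FALSE]) %% 2)
    }
    y <- y + fn$coefficients[t] * sign
  }
  y
}

#' Fraction of variance explained by the top-k WH coefficients
#'
#' The constant (empty-set) term carries no variance and is excluded from
#' both numerator and denominator. Ties in magnitude are broken by ascending
#' mask index for determinism.
#'
#' @param spectrum a `wh_spectrum`.
#' @param up_to report fractions for k = 1..up_to (default: all non-constant
#'   coefficients present).
#' @return numeric vector, entry k = fraction of total squared non-constant
#'   coefficient mass captured by the k largest.
#' @export
variance_explained_curve <- function(spectrum, up_to = NULL) {
  stopifnot(inherits(spectrum, "wh_spectrum"))
  co <- spectrum$coefficients
  co <- co[mask_order(names(co)) > 0]
  tot <- sum(co^2)
  if (tot == 0) stop("degenerate landscape: zero variance (constant function)")
  ord <- order(-co^2, mask_index(names(co)))
  sq <- co[ord]^2
  if (is.null(up_to)) up_to <- length(sq)
  up_to <- min(up_to, length(sq))
  cumsum(sq)[seq_len(up_to)] / tot
}

#' @export
print.wh_spectrum <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("WH spectrum: d = %d, scale = %s, %d stored / %d nonzero\n",
              x$d, x$scale, length(x$coefficients), nz))
  invisible(x)
}

#' @export
print.pbf <- function(x, ...) {
  cat(sprintf("pseudo-Boolean function: d = %d, %d terms\n",
              x$d, length(x$masks)))
  if (length(x$masks) > 0) {
    ord <- mask_order(x$masks)
    for (t in seq_along(x$masks)) {
      cat(sprintf("  {%s} (order %d): %g\n",
                  paste(sites_from_mask(x$masks[t]), collapse = ","),
                  ord[t], x$coefficients[t]))
    }
  }
  invisible(x)
}
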