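# Subset masks are length-d bitstrings: character i is "1" iff site i is in
# the subset. Strings (not integers) so that d > 30 works unchanged.

#' Build a subset mask from site indices
#'
#' @param sites integer vector of 1-based site indices (may be empty).
#' @param d total number of sites.
#' @return a length-d bitstring, character i equal to "1" iff site i is in
#'   `sites`.
#' @export
mask_from_sites <- function(sites, d) {
  stopifnot(d >= 1, all(sites >= 1), all(sites <= d))
  bits <- rep.int("0", d)
  bits[unique(as.integer(sites))] <- "1"
  paste(bits, collapse = "")
}

#' Site indices of a subset mask
#'
#' @param mask a length-d bitstring.
#' @return integer vector of 1-based sites present in the mask.
#' @export
sites_from_mask <- function(mask) {
  which(strsplit(mask, "", fixed = TRUE)[[1]] == "1")
}

#' Interaction order (cardinality) of each mask
#'
#' @param masks character vector of bitstrings.
#' @return integer vector of subset sizes.
#' @export
mask_order <- function(masks) {
  vapply(strsplit(masks, "", fixed = TRUE),
         function(b) sum(b == "1"), integer(1))
}

# Integer value of a mask under the canonical index<->subset bijection
# (bit i-1 of the index <-> site i). Only valid for d <= 30.
mask_index <- function(masks) {
  vapply(strsplit(masks, "", fixed = TRUE), function(b) {
    sum(2^(which(b == "1") - 1))
  }, numeric(1))
}

# All 2^d masks in canonical enumeration order (index j -> its bit pattern).
all_masks <- function(d) {
  stopifnot(d >= 1, d <= 25)
  j <- 0:(2^d - 1)
  cols <- lapply(seq_len(d), function(i) (j %/% 2^(i - 1)) %% 2)
  do.call(paste0, cols)
}

# 0/1 matrix (n x d) -> bitstrings; row-wise.
bits_to_masks <- function(bits) {
  do.call(paste0, lapply(seq_len(ncol(bits)), function(i) bits[, i]))
}
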