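# Sequence -> {-1,+1}^d encodings. Two schemes:
#   binary-site: one bit per mutational site ("0" = reference -> +1);
#   one-hot-block: one indicator block per categorical site (amino acids);
#     the observed letter's position is the designated bit (-1), all other
#     positions +1, so reference/absent states map to +1.

#' Declare a site encoding
#'
#' @param scheme `"binary-site"` for 0/1 mutation strings, or
#'   `"one-hot-block"` for categorical (e.g. amino-acid) strings.
#' @param n_sites number of sequence positions.
#' @param alphabet character vector of allowed letters per site (one-hot
#'   scheme only); the same alphabet is used at every site.
#' @return a `site_encoding` with total binary width `d`.
#' @export
site_encoding <- function(scheme = c("binary-site", "one-hot-block"),
                          n_sites, alphabet = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n_sites >= 1)
  if (scheme == "binary-site") {
    widths <- rep.int(1L, n_sites)
  } else {
    if (is.null(alphabet) || length(alphabet) < 2) {
      stop("one-hot-block encoding needs an alphabet of at least 2 letters")
    }
    if (anyDuplicated(alphabet)) stop("alphabet letters must be unique")
    widths <- rep.int(length(alphabet), n_sites)
  }
  structure(list(scheme = scheme, n_sites = as.integer(n_sites),
                 alphabet = alphabet, widths = widths,
                 d = as.integer(sum(widths))),
            class = "site_encoding")
}

#' Encode sequences as +/-1 matrices
#'
#' Deterministic and invertible on the encoding's declared domain; see
#' [decode_sequences()].
#'
#' @param sequences character vector of sequences (each of `n_sites` letters).
#' @param encoding a `site_encoding`.
#' @return n x d matrix with entries in {-1, +1}.
#' @export
encode_sequences <- function(sequences, encoding) {
  stopifnot(inherits(encoding, "site_encoding"))
  chars <- strsplit(sequences, "", fixed = TRUE)
  bad <- which(lengths(chars) != encoding$n_sites)
  if (length(bad) > 0) {
    stop("sequence ", bad[1], " has length ", lengths(chars)[bad[1]],
         ", expected ", encoding$n_sites)
  }
  n <- length(sequences)
  if (encoding$scheme == "binary-site") {
    M <- matrix(unlist(chars), nrow = n, byrow = TRUE)
    if (!all(M %in% c("0", "1"))) stop("unknown symbol: expected 0/1 string")
    X <- 1 - 2 * (M == "1")
  } else {
    X <- matrix(1, nrow = n, ncol = encoding$d)
    w <- length(encoding$alphabet)
    for (s in seq_len(encoding$n_sites)) {
      letter <- vapply(chars, `[[`, character(1), s)
      pos <- match(letter, encoding$alphabet)
      if (anyNA(pos)) {
        stop("unknown symbol '", letter[which(is.na(pos))[1]],
             "' at site ", s)
      }
      X[cbind(seq_len(n), (s - 1) * w + pos)] <- -1
    }
  }
  storage.mode(X) <- "double"
  X
}

#' Decode +/-1 matrices back to sequences
#'
#' @param X n x d matrix produced by [encode_sequences()].
#' @param encoding the `site_encoding` used to produce it.
#' @return character vector of sequences.
#' @export
decode_sequences <- function(X, encoding) {
  stopifnot(inherits(encoding, "site_encoding"), ncol(X) == encoding$d)
  if (encoding$scheme == "binary-site") {
    M <- ifelse(X < 0, "1", "0")
    return(apply(M, 1, paste, collapse = ""))
  }
  w <- length(encoding$alphabet)
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    letters_i <- character(encoding$n_sites)
    for (s in seq_len(encoding$n_sites)) {
      block <- X[i, (s - 1) * w + seq_len(w)]
      hit <- which(block < 0)
      if (length(hit) != 1) {
        stop("row ", i, " site ", s, " does not have exactly one ",
             "designated-state bit")
      }
      letters_i[s] <- encoding$alphabet[hit]
    }
    out[i] <- paste(letters_i, collapse = "")
  }
  out
}
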