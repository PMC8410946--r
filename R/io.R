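# Plain-text serialization: spectra as TSV/JSON, landscapes as CSV,
# sampling plans as JSON.

#' Write / read a spectrum as TSV
#'
#' Columns: mask (bitstring), order, coefficient, scale.
#'
#' @param spectrum a `wh_spectrum`.
#' @param path file path.
#' @return `read_spectrum_tsv` returns a `wh_spectrum`.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "wh_spectrum"))
  df <- data.frame(mask = names(spectrum$coefficients),
                   order = mask_order(names(spectrum$coefficients)),
                   coefficient = unname(spectrum$coefficients),
                   scale = spectrum$scale,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer",
                                         "numeric", "character"))
  d <- if (nrow(df) > 0) nchar(df$mask[1]) else
    stop("empty spectrum file (d cannot be inferred)")
  co <- df$coefficient
  names(co) <- df$mask
  wh_spectrum(co, d, unique(df$scale))
}

#' Write / read a spectrum as JSON
#'
#' @inheritParams write_spectrum_tsv
#' @export
write_spectrum_json <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "wh_spectrum"))
  obj <- list(d = spectrum$d, scale = spectrum$scale,
              masks = names(spectrum$coefficients),
              coefficients = unname(spectrum$coefficients))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum_json
#' @export
read_spectrum_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- as.numeric(obj$coefficients)
  names(co) <- as.character(obj$masks)
  wh_spectrum(co, as.integer(obj$d), obj$scale)
}

#' Write / read a full landscape as CSV (index, value)
#'
#' @param landscape a `wh_landscape`.
#' @param path file path.
#' @export
write_landscape_csv <- function(landscape, path) {
  stopifnot(inherits(landscape, "wh_landscape"))
  utils::write.csv(data.frame(index = seq_along(landscape$values) - 1,
                              value = landscape$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landscape_csv
#' @export
read_landscape_csv <- function(path) {
  df <- utils::read.csv(path)
  wh_landscape(df$value[order(df$index)])
}

#' Write / read a dataset of (sequence, fitness) pairs as CSV
#'
#' @param sequences character vector (bitstrings or residue strings).
#' @param fitness numeric vector.
#' @param path file path.
#' @export
write_dataset_csv <- function(sequences, fitness, path) {
  utils::write.csv(data.frame(sequence = sequences, fitness = fitness),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(sequence = "character"))
  df
}
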