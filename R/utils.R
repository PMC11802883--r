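## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Hamming distance between equal-length DNA strings
#'
#' Number of positions at which two strings of identical length differ.
#' `b` may be a vector; the distance of `a` to each element is returned.
#'
#' @param a Single character string.
#' @param b Character vector, each element the same length as `a`.
#' @return Integer vector of distances.
#' @export
hamming <- function(a, b) {
  la <- nchar(a)
  if (any(nchar(b) != la)) {
    stop("hamming() requires equal-length strings")
  }
  ai <- utf8ToInt(a)
  vapply(b, function(x) sum(utf8ToInt(x) != ai), integer(1), USE.NAMES = FALSE)
}

## Convert a character vector of equal-length sequences into an
## integer matrix (one row per sequence) for fast vectorised distance work.
seq_int_matrix <- function(x, len) {
  matrix(utf8ToInt(paste(x, collapse = "")), ncol = len, byrow = TRUE)
}

## Hamming distance of one candidate (integer vector) against all rows.
row_hamming <- function(mat, cand_int) {
  if (nrow(mat) == 0L) return(integer(0))
  as.integer(rowSums(mat != rep(cand_int, each = nrow(mat))))
}

## Strict-schema TSV reader: all columns character unless coerced later.
read_tsv_strict <- function(path, required, what = "file") {
  if (!file.exists(path)) {
    stop(sprintf("%s not found: %s", what, path))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s %s is missing column(s): %s",
                 what, path, paste(missing, collapse = ", ")))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## Median with the conventional even-size midpoint interpolation
## (stats::median already does this; kept as a named alias so the
## convention is explicit at call sites).
midpoint_median <- function(x) stats::median(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
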