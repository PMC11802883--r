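## Barcode map: the lookup from 20-bp strain barcodes to strain/gene
## identity that every downstream join uses.

#' Construct a barcode map
#'
#' A barcode map ties each fixed-length DNA barcode to a strain, the gene
#' (ORF) deleted in that strain, and the strain class (`mutant` or
#' `wildtype`). In the pooled origin-occupancy screen each deletion strain
#' carries one unique barcode integrated next to the tracked replication
#' origin; the wild-type control population may share a gene label across
#' many barcodes.
#'
#' @param barcode Character vector of barcode sequences, all the same
#'   length, alphabet restricted to A/C/G/T, no duplicates.
#' @param strain_id Character vector of unique strain identifiers.
#' @param gene Character vector of gene/ORF identifiers. A gene may be
#'   carried by several barcodes only when those rows are `wildtype`.
#' @param strain_class Character vector, each element `"mutant"` or
#'   `"wildtype"`.
#' @return An object of class `barcode_map`: a data.frame with columns
#'   `barcode`, `strain_id`, `gene`, `strain_class` and attribute
#'   `barcode_length`.
#' @export
barcode_map <- function(barcode, strain_id, gene, strain_class) {
  barcode <- toupper(as.character(barcode))
  n <- length(barcode)
  stopifnot(length(strain_id) == n, length(gene) == n,
            length(strain_class) == n)
  if (n == 0L) stop("barcode map is empty")

  L <- nchar(barcode[1])
  bad_len <- nchar(barcode) != L
  if (any(bad_len)) {
    stop(sprintf("barcode length differs from first row's length (%d): %s",
                 L, barcode[which(bad_len)[1]]))
  }
  if (!all(grepl("^[ACGT]+$", barcode))) {
    bad <- barcode[!grepl("^[ACGT]+$", barcode)][1]
    stop(sprintf("invalid alphabet in barcode (only A/C/G/T allowed): %s", bad))
  }
  dup <- barcode[duplicated(barcode)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate barcode: %s", dup[1]))
  }
  if (anyDuplicated(strain_id)) {
    stop(sprintf("duplicate strain_id: %s", strain_id[duplicated(strain_id)][1]))
  }
  if (!all(strain_class %in% c("mutant", "wildtype"))) {
    stop("strain_class must be 'mutant' or 'wildtype'")
  }
  mut <- strain_class == "mutant"
  if (anyDuplicated(gene[mut])) {
    stop(sprintf("gene mapped to multiple mutant barcodes: %s",
                 gene[mut][duplicated(gene[mut])][1]))
  }

  out <- data.frame(barcode = barcode, strain_id = strain_id,
                    gene = gene, strain_class = strain_class,
                    stringsAsFactors = FALSE)
  attr(out, "barcode_length") <- L
  class(out) <- c("barcode_map", "data.frame")
  out
}

#' Load a barcode map from a TSV file
#'
#' Expects a header row and columns `barcode`, `strain_id`, `gene`,
#' `strain_class`. Row order is preserved. Validation errors (duplicate
#' barcode, non-ACGT character, inconsistent length) are hard errors
#' naming the offending value.
#'
#' @param path Path to the TSV file.
#' @return A [barcode_map] object.
#' @export
load_barcode_map <- function(path) {
  df <- read_tsv_strict(path, c("barcode", "strain_id", "gene", "strain_class"),
                        what = "barcode map")
  barcode_map(df$barcode, df$strain_id, df$gene, df$strain_class)
}

#' Write a barcode map to TSV
#'
#' @param map A [barcode_map].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_barcode_map <- function(map, path) {
  write_tsv(as.data.frame(map)[, c("barcode", "strain_id", "gene",
                                   "strain_class")], path)
}

#' @export
print.barcode_map <- function(x, ...) {
  cat(sprintf("barcode_map: %d barcodes (L = %d); %d mutant, %d wildtype\n",
              nrow(x), attr(x, "barcode_length"),
              sum(x$strain_class == "mutant"),
              sum(x$strain_class == "wildtype")))
  invisible(x)
}
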