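## Barcode extraction and counting: raw amplicon reads -> per-sample
## barcode counts with QC tallies.

UNASSIGNED_REASONS <- c("no_anchor", "short_read", "unknown_barcode",
                        "ambiguous_correction")

#' Describe the layout of a barcode amplicon read
#'
#' The barcode is located by an anchor sequence expected immediately 5' of
#' it. The anchor may begin anywhere inside `search_window` (a 0-based
#' half-open interval of read positions); the leftmost acceptable position
#' wins. `anchor` may be the empty string, in which case the barcode is
#' taken directly at the window start.
#'
#' @param anchor DNA string expected immediately 5' of the barcode
#'   (default `"CGTACGCTGC"`; configurable because amplicon primer layouts
#'   differ between barcode libraries).
#' @param barcode_length Barcode length in bp (default 20).
#' @param anchor_max_mismatch Maximum number of mismatches tolerated when
#'   locating the anchor (default 0).
#' @param search_window Integer pair `(start, end)`, 0-based half-open
#'   interval of positions at which the anchor may begin. `NULL` (default)
#'   means the whole read.
#' @return An object of class `read_structure`.
#' @export
read_structure <- function(anchor = "CGTACGCTGC", barcode_length = 20L,
                           anchor_max_mismatch = 0L, search_window = NULL) {
  anchor <- toupper(anchor)
  stopifnot(barcode_length > 0L, anchor_max_mismatch >= 0L)
  if (nchar(anchor) > 0L && !grepl("^[ACGT]+$", anchor)) {
    stop("anchor must contain only A/C/G/T")
  }
  if (!is.null(search_window)) {
    stopifnot(length(search_window) == 2L,
              search_window[1] >= 0L, search_window[2] > search_window[1])
  }
  structure(list(anchor = anchor,
                 barcode_length = as.integer(barcode_length),
                 anchor_max_mismatch = as.integer(anchor_max_mismatch),
                 search_window = search_window),
            class = "read_structure")
}

## Locate the anchor in each read. Returns 1-based position of the first
## barcode base, or NA where no acceptable anchor exists in the window.
## Vectorised exact path; per-position scan when mismatches are allowed.
locate_anchor <- function(reads, structure) {
  alen <- nchar(structure$anchor)
  nmax <- nchar(reads)
  win <- structure$search_window
  wstart <- if (is.null(win)) 0L else win[1]
  wend_excl <- if (is.null(win)) max(nmax) else win[2]  # anchor start < wend_excl

  if (alen == 0L) {
    return(rep(wstart + 1L, length(reads)))
  }

  if (structure$anchor_max_mismatch == 0L) {
    ## search region: anchor may begin at 0-based p in [wstart, wend_excl)
    region <- substr(reads, wstart + 1L, wend_excl + alen - 1L)
    p <- regexpr(structure$anchor, region, fixed = TRUE)
    pos <- ifelse(p > 0L, wstart + as.integer(p) + alen, NA_integer_)
    return(as.integer(pos))
  }

  ## mismatch-tolerant scan, leftmost acceptable position wins
  anchor_chars <- strsplit(structure$anchor, "")[[1]]
  pos <- rep(NA_integer_, length(reads))
  for (p0 in wstart:(wend_excl - 1L)) {
    todo <- is.na(pos) & (nmax >= p0 + alen)
    if (!any(todo)) next
    seg <- substr(reads[todo], p0 + 1L, p0 + alen)
    mism <- integer(length(seg))
    for (i in seq_len(alen)) {
      mism <- mism + (substr(seg, i, i) != anchor_chars[i])
    }
    ok <- mism <= structure$anchor_max_mismatch
    pos[which(todo)[ok]] <- p0 + alen + 1L
  }
  pos
}

## Vectorised core of extract_barcode: returns a list with the assigned
## barcode (NA where unassigned) and the reason for unassigned reads.
extract_barcodes_vec <- function(reads, structure, map,
                                 policy = c("exact", "hamming1")) {
  policy <- match.arg(policy)
  L <- structure$barcode_length
  if (L != attr(map, "barcode_length")) {
    stop("read_structure barcode_length does not match the barcode map")
  }
  n <- length(reads)
  barcode <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  pos <- locate_anchor(reads, structure)
  reason[is.na(pos)] <- "no_anchor"

  has_anchor <- !is.na(pos)
  short <- has_anchor & (nchar(reads) < pos + L - 1L)
  reason[short] <- "short_read"

  ok <- has_anchor & !short
  cand <- substr(reads[ok], pos[ok], pos[ok] + L - 1L)
  hit <- match(cand, map$barcode)
  known <- !is.na(hit)
  barcode[which(ok)[known]] <- map$barcode[hit[known]]

  if (policy == "exact") {
    reason[which(ok)[!known]] <- "unknown_barcode"
  } else {
    ## hamming1: unique map barcode at distance 1, else unassigned
    miss_idx <- which(ok)[!known]
    if (length(miss_idx) > 0L) {
      uq <- unique(cand[!known])
      map_mat <- seq_int_matrix(map$barcode, L)
      corr <- vapply(uq, function(b) {
        d <- row_hamming(map_mat, utf8ToInt(b))
        w <- which(d == 1L)
        if (length(w) == 1L) map$barcode[w]
        else if (length(w) > 1L) ".ambiguous." else ".unknown."
      }, character(1))
      res <- corr[match(cand[!known], uq)]
      barcode[miss_idx] <- ifelse(res %in% c(".ambiguous.", ".unknown."),
                                  NA_character_, res)
      reason[miss_idx] <- ifelse(res == ".ambiguous.",
                                 "ambiguous_correction",
                          ifelse(res == ".unknown.", "unknown_barcode",
                                 NA_character_))
    }
  }
  list(barcode = barcode, reason = reason)
}

#' Extract the barcode from a single read
#'
#' Locates the anchor within the search window (leftmost acceptable
#' position wins), takes the next `barcode_length` bases as the candidate
#' barcode and resolves it against the map. Under `exact` policy the
#' candidate is assigned iff present in the map; under `hamming1` an
#' unmatched candidate is corrected to the unique map barcode at Hamming
#' distance 1 if one exists. Unassignable reads are data, not errors.
#'
#' @param read A single DNA read (character string).
#' @param structure A [read_structure].
#' @param map A [barcode_map].
#' @param policy `"exact"` (default) or `"hamming1"`.
#' @return A list with `barcode` (string or `NA`) and `reason` (`NA` when
#'   assigned; otherwise one of `no_anchor`, `short_read`,
#'   `unknown_barcode`, `ambiguous_correction`).
#' @export
extract_barcode <- function(read, structure, map,
                            policy = c("exact", "hamming1")) {
  stopifnot(length(read) == 1L, nchar(read) > 0L)
  r <- extract_barcodes_vec(toupper(read), structure, map, policy)
  list(barcode = r$barcode[1], reason = r$reason[1])
}

#' Sample metadata for one sequencing sample
#'
#' @param sample_id Sample identifier.
#' @param role `"IP"` (immunoprecipitated chromatin) or `"input"` (total
#'   chromatin).
#' @param timepoint Minutes after release into S phase; the screen design
#'   collects 40 and 80 min.
#' @param replicate Replicate screen index (integer).
#' @return An object of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, role = c("IP", "input"),
                        timepoint, replicate) {
  role <- match.arg(role)
  structure(list(sample_id = as.character(sample_id), role = role,
                 timepoint = as.integer(timepoint),
                 replicate = as.integer(replicate)),
            class = "sample_meta")
}

#' Count barcodes in a sample's reads
#'
#' Applies [extract_barcode] to every read and tallies assignments.
#' Every map barcode appears in the output, with count 0 if unseen.
#' The conservation invariant holds: `assigned + unassigned = total` and
#' `assigned = sum(counts)`.
#'
#' @param reads Either a path to a FASTQ file (optionally
#'   gzip-compressed) or a character vector of read sequences.
#' @param map A [barcode_map].
#' @param structure A [read_structure].
#' @param policy Barcode matching policy, `"exact"` or `"hamming1"`.
#' @param sample A [sample_meta], or `NULL`.
#' @return An object of class `sample_counts`: list with `sample`,
#'   `counts` (named integer vector over all map barcodes),
#'   `total_reads`, `assigned_reads`, `unassigned_reads` and
#'   `unassigned_by_reason`.
#' @export
count_barcodes <- function(reads, map, structure = read_structure(),
                           policy = c("exact", "hamming1"), sample = NULL) {
  policy <- match.arg(policy)
  if (nrow(map) == 0L) stop("barcode map is empty")
  if (length(reads) == 1L && grepl("[./\\\\]", reads)) {
    ## a single string containing path characters is a FASTQ path
    if (!file.exists(reads)) stop(sprintf("FASTQ file not found: %s", reads))
    reads <- read_fastq_sequences(reads)
  }
  n <- length(reads)
  counts <- stats::setNames(integer(nrow(map)), map$barcode)
  reason_tab <- stats::setNames(integer(length(UNASSIGNED_REASONS)),
                                UNASSIGNED_REASONS)
  if (n > 0L) {
    r <- extract_barcodes_vec(toupper(reads), structure, map, policy)
    tab <- table(factor(r$barcode, levels = map$barcode))
    counts[] <- as.integer(tab)
    rtab <- table(factor(r$reason, levels = UNASSIGNED_REASONS))
    reason_tab[] <- as.integer(rtab)
  }
  out <- list(sample = sample, counts = counts, total_reads = n,
              assigned_reads = sum(counts),
              unassigned_reads = n - sum(counts),
              unassigned_by_reason = reason_tab)
  class(out) <- "sample_counts"
  out
}

#' Read the sequences of a FASTQ file
#'
#' Plain or gzip-compressed FASTQ. Malformed records (truncated record or
#' header/separator line violations) are hard errors reporting the record
#' index. Quality strings are read but ignored.
#'
#' @param path FASTQ file path.
#' @return Character vector of read sequences.
#' @export
read_fastq_sequences <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(sprintf("malformed FASTQ %s: truncated record %d", path,
                 n %/% 4L + 1L))
  }
  if (n == 0L) return(character(0))
  heads <- seq(1L, n, by = 4L)
  seps <- seq(3L, n, by = 4L)
  bad_h <- which(!startsWith(lines[heads], "@"))
  if (length(bad_h) > 0L) {
    stop(sprintf("malformed FASTQ %s: record %d header does not start with '@'",
                 path, bad_h[1]))
  }
  bad_s <- which(!startsWith(lines[seps], "+"))
  if (length(bad_s) > 0L) {
    stop(sprintf("malformed FASTQ %s: record %d separator does not start with '+'",
                 path, bad_s[1]))
  }
  lines[seq(2L, n, by = 4L)]
}

#' @export
print.sample_counts <- function(x, ...) {
  id <- if (!is.null(x$sample)) x$sample$sample_id else "<unnamed>"
  cat(sprintf(
    "sample_counts %s: %d reads, %d assigned (%.1f%%), %d unassigned\n",
    id, x$total_reads, x$assigned_reads,
    if (x$total_reads > 0) 100 * x$assigned_reads / x$total_reads else 0,
    x$unassigned_reads))
  invisible(x)
}

#' Write per-sample barcode counts and QC to TSV
#'
#' @param counts A `sample_counts` object.
#' @param map The [barcode_map] used for counting.
#' @param path Output TSV path (columns barcode, strain_id, gene,
#'   strain_class, count).
#' @return The path, invisibly.
#' @export
write_counts <- function(counts, map, path) {
  df <- data.frame(barcode = map$barcode, strain_id = map$strain_id,
                   gene = map$gene, strain_class = map$strain_class,
                   count = as.integer(counts$counts[map$barcode]),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a counts TSV back into a `sample_counts` object
#'
#' @param path Counts TSV written by [write_counts].
#' @param map A [barcode_map]; counted barcodes must all exist in it.
#' @param sample Optional [sample_meta] to attach.
#' @param total_reads,unassigned_reads Optional QC totals (from the QC
#'   TSV); when missing, totals are taken as the assigned sum.
#' @return A `sample_counts` object.
#' @export
read_counts <- function(path, map, sample = NULL, total_reads = NULL,
                        unassigned_reads = NULL) {
  df <- read_tsv_strict(path, c("barcode", "count"), what = "counts table")
  unknown <- setdiff(df$barcode, map$barcode)
  if (length(unknown) > 0L) {
    stop(sprintf("counts table %s contains barcode absent from map: %s",
                 path, unknown[1]))
  }
  counts <- stats::setNames(integer(nrow(map)), map$barcode)
  counts[df$barcode] <- as.integer(df$count)
  assigned <- sum(counts)
  unassigned <- unassigned_reads %||% 0L
  total <- total_reads %||% (assigned + unassigned)
  out <- list(sample = sample, counts = counts, total_reads = total,
              assigned_reads = assigned, unassigned_reads = total - assigned,
              unassigned_by_reason = NULL)
  class(out) <- "sample_counts"
  out
}
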