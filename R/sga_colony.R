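## Suppressor-screen colony scoring: plate-median normalization of colony
## sizes, treated/control growth ratio per mutant, suppressor calling.

#' Construct a colony plate
#'
#' One arrayed plate of colony sizes from a synthetic genetic array (SGA)
#' screen, either the untreated control (YPD) or the drug-treated
#' condition.
#'
#' @param plate_id Plate identifier.
#' @param condition `"control"` or `"treated"`.
#' @param row,column Integer well coordinates; each (row, column) pair
#'   must be unique on the plate.
#' @param strain_id Strain occupying the well.
#' @param colony_size Non-negative colony size (arbitrary area units).
#' @return An object of class `colony_plate` (a data.frame).
#' @export
colony_plate <- function(plate_id, condition = c("control", "treated"),
                         row, column, strain_id, colony_size) {
  condition <- match.arg(condition)
  n <- length(strain_id)
  stopifnot(length(row) == n, length(column) == n, length(colony_size) == n)
  if (any(colony_size < 0)) stop("colony sizes must be non-negative")
  if (anyDuplicated(paste(row, column))) {
    stop("duplicate (row, column) well on plate")
  }
  out <- data.frame(plate_id = as.character(plate_id), condition = condition,
                    row = as.integer(row), column = as.integer(column),
                    strain_id = as.character(strain_id),
                    colony_size = as.numeric(colony_size),
                    stringsAsFactors = FALSE)
  class(out) <- c("colony_plate", "data.frame")
  out
}

#' Load colony plates from a TSV file
#'
#' Columns: `plate_id`, `condition`, `row`, `column`, `strain_id`, `size`.
#'
#' @param path TSV path.
#' @return List of `colony_plate` objects, one per plate_id.
#' @export
load_colony_plates <- function(path) {
  df <- read_tsv_strict(path, c("plate_id", "condition", "row", "column",
                                "strain_id", "size"), what = "plate table")
  lapply(split(df, df$plate_id), function(p) {
    colony_plate(p$plate_id[1], p$condition[1], as.integer(p$row),
                 as.integer(p$column), p$strain_id, as.numeric(p$size))
  })
}

#' Plate-median normalization of colony sizes
#'
#' Each colony size is divided by the median colony size on the plate, so
#' the plate median of normalized sizes is 1 and scores are invariant to
#' pinning density or imaging scale. The median is taken over all wells,
#' zeros included; zero-size wells normalize to 0 and are removed later
#' by the scoring step.
#'
#' @param plate A `colony_plate`.
#' @param include_zeros Whether zero wells enter the median (default
#'   TRUE).
#' @return Named numeric vector of normalized sizes per strain.
#' @export
normalize_plate <- function(plate, include_zeros = TRUE) {
  sizes <- plate$colony_size
  m <- midpoint_median(if (include_zeros) sizes else sizes[sizes > 0])
  if (is.na(m) || m == 0) stop("plate median colony size is 0")
  stats::setNames(sizes / m, plate$strain_id)
}

#' Score a suppressor screen from control and treated plates
#'
#' Per strain, the score is the plate-median-normalized colony size on
#' the treated plate divided by that on the control plate. Strains with a
#' normalized size of 0 in either condition are removed before scoring;
#' strains present in only one condition are dropped with a warning. A
#' strain is called a suppressor when its score strictly exceeds the
#' fold-change threshold `F`. If a strain appears on several plates of
#' the same condition (replicates), its normalized sizes are averaged.
#'
#' @param control_plates,treated_plates A `colony_plate` or list thereof.
#' @param fc_threshold Fold-change call threshold `F` (default 1.5;
#'   strict `>`).
#' @param include_zeros Passed to [normalize_plate].
#' @return An object of class `suppressor_table`: data.frame sorted by
#'   descending score (the waterfall order) with columns `strain_id`,
#'   `norm_control`, `norm_treated`, `score`, `call`.
#' @export
suppressor_scores <- function(control_plates, treated_plates,
                              fc_threshold = 1.5, include_zeros = TRUE) {
  as_list <- function(x) if (inherits(x, "colony_plate")) list(x) else x
  norm_by_strain <- function(plates) {
    v <- unlist(lapply(as_list(plates), normalize_plate,
                       include_zeros = include_zeros))
    tapply(v, names(v), mean)  # average replicate plates per strain
  }
  ctrl <- norm_by_strain(control_plates)
  trt <- norm_by_strain(treated_plates)

  shared <- intersect(names(ctrl), names(trt))
  only_one <- union(setdiff(names(ctrl), shared), setdiff(names(trt), shared))
  if (length(only_one) > 0L) {
    warning(sprintf("%d strain(s) present in one condition only; dropped",
                    length(only_one)))
  }
  ctrl <- ctrl[shared]; trt <- trt[shared]
  keep <- ctrl > 0 & trt > 0  # zero-normalized data removed before scoring
  ctrl <- ctrl[keep]; trt <- trt[keep]
  if (length(ctrl) == 0L) stop("no strains with positive sizes in both conditions")

  out <- data.frame(strain_id = names(ctrl),
                    norm_control = as.numeric(ctrl),
                    norm_treated = as.numeric(trt),
                    score = as.numeric(trt / ctrl),
                    stringsAsFactors = FALSE)
  out$call <- out$score > fc_threshold
  out <- out[order(-out$score, out$strain_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fc_threshold") <- fc_threshold
  class(out) <- c("suppressor_table", "data.frame")
  out
}

#' @export
print.suppressor_table <- function(x, ...) {
  cat(sprintf("suppressor_table: %d strains scored, %d called (score > %.2g)\n",
              nrow(x), sum(x$call), attr(x, "fc_threshold")))
  invisible(x)
}

#' Write a suppressor table (waterfall order) to TSV
#'
#' @param tab A `suppressor_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_suppressor_table <- function(tab, path) {
  write_tsv(as.data.frame(tab), path)
}
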