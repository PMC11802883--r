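## Screen scoring: absence filter, median normalization, IP/input ratios,
## replicate averaging, log2 fold change against a wild-type baseline, and
## four-class hit calling.

HIT_CLASSES <- c("down_both", "up_both", "down_40_only", "down_80_only",
                 "other")

#' Configuration of the screen-scoring procedure
#'
#' @param absence_fraction Fraction of an input sample's total reads below
#'   which a barcode is considered absent from the pool and excluded.
#'   Default `2.5e-5` (0.0025%). The boundary is strict: a barcode exactly
#'   at the cutoff is retained.
#' @param hit_threshold Hit-calling threshold `tau` in log2 units
#'   (default 1.25). All class comparisons against `tau` are strict.
#' @param baseline_policy What the per-timepoint fold change is relative
#'   to: `"wildtype_median"` (default; median mean-ratio over the
#'   wild-type control barcodes), `"all_median"` (median over all retained
#'   entries) or `"none"` (baseline 1, i.e. uncentred ratios).
#' @param replicate_combine How replicate ratios are combined:
#'   `"mean_of_ratios"` (default; arithmetic mean of raw ratios, then
#'   log2) or `"mean_of_logs"` (mean of log2 ratios; zero ratios floored
#'   first).
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(absence_fraction = 2.5e-5, hit_threshold = 1.25,
                          baseline_policy = c("wildtype_median",
                                              "all_median", "none"),
                          replicate_combine = c("mean_of_ratios",
                                                "mean_of_logs")) {
  baseline_policy <- match.arg(baseline_policy)
  replicate_combine <- match.arg(replicate_combine)
  stopifnot(absence_fraction >= 0, absence_fraction < 1, hit_threshold > 0)
  structure(list(absence_fraction = absence_fraction,
                 hit_threshold = hit_threshold,
                 baseline_policy = baseline_policy,
                 replicate_combine = replicate_combine),
            class = "screen_config")
}

#' Absence filter on an input sample
#'
#' Barcodes whose read number falls strictly below
#' `absence_fraction * total_reads` of the input sample are considered
#' absent from the pool and excluded; a barcode exactly at the cutoff is
#' retained.
#'
#' @param input_counts A `sample_counts` object for an input sample.
#' @param cfg A [screen_config].
#' @return Character vector of retained barcodes.
#' @export
filter_absent <- function(input_counts, cfg = screen_config()) {
  if (!is.null(input_counts$sample) && input_counts$sample$role != "input") {
    stop("filter_absent() must be applied to an input sample")
  }
  if (input_counts$total_reads == 0L) stop("empty input sample")
  cutoff <- cfg$absence_fraction * input_counts$total_reads
  names(input_counts$counts)[input_counts$counts >= cutoff]
}

#' Median-normalize barcode counts over a retained set
#'
#' Each retained barcode's count is divided by the median count over the
#' retained barcodes in the same sample, so the median normalized score
#' is 1 and scores are invariant to sequencing depth.
#'
#' @param counts A `sample_counts` object.
#' @param retained Character vector of retained barcodes (non-empty).
#' @return Named numeric vector of scores over `retained`.
#' @export
median_normalize <- function(counts, retained) {
  if (length(retained) == 0L) stop("retained barcode set is empty")
  x <- counts$counts[retained]
  if (anyNA(x)) stop("retained barcode missing from sample counts")
  m <- midpoint_median(x)
  if (m == 0) stop("degenerate sample: median count over retained barcodes is 0")
  x / m
}

#' Per-barcode IP/input occupancy ratio
#'
#' Divides median-normalized IP scores by the corresponding input scores.
#' Both score vectors must cover the same retained set. A barcode with IP
#' count 0 has score 0 and hence ratio 0; a retained barcode can never
#' have input score 0 (the absence filter guarantees a positive count).
#'
#' @param ip_scores,input_scores Named score vectors from
#'   [median_normalize] over the same retained set.
#' @return Named numeric vector of ratios.
#' @export
ip_over_input <- function(ip_scores, input_scores) {
  shared <- intersect(names(ip_scores), names(input_scores))
  if (length(shared) != length(ip_scores) ||
      length(shared) != length(input_scores)) {
    stop("IP and input scores must be computed over the same retained set")
  }
  inp <- input_scores[shared]
  stopifnot(all(inp > 0))
  ip_scores[shared] / inp
}

## Score one (timepoint, replicate): filter on the input, normalize both
## samples over the retained set, ratio. Returns list(ratio, retained).
score_one_replicate <- function(ip_counts, input_counts, cfg) {
  retained <- filter_absent(input_counts, cfg)
  if (length(retained) == 0L) stop("no barcodes retained after absence filter")
  ratio <- ip_over_input(median_normalize(ip_counts, retained),
                         median_normalize(input_counts, retained))
  list(ratio = ratio, retained = retained)
}

#' Average replicate ratios per barcode and timepoint
#'
#' A barcode contributes only if it is retained in every replicate's
#' input at both timepoints (the overlapping-ORF intersection rule);
#' the replicate ratios are then combined by arithmetic mean (default).
#'
#' @param ratios Nested list: `ratios[[timepoint]][[replicate]]`, each a
#'   named ratio vector from one replicate at that timepoint.
#' @param cfg A [screen_config].
#' @return List with `mean_ratio` (named list per timepoint: named
#'   numeric vectors over the shared barcode set), `barcodes` (the shared
#'   set) and `n_replicates` (per timepoint).
#' @export
merge_replicates <- function(ratios, cfg = screen_config()) {
  stopifnot(length(ratios) >= 1L)
  shared <- Reduce(intersect, unlist(lapply(ratios, function(tp)
    lapply(tp, names)), recursive = FALSE))
  if (length(shared) == 0L) stop("no overlapping barcodes across replicates")
  mean_ratio <- lapply(ratios, function(tp) {
    mat <- vapply(tp, function(r) r[shared], numeric(length(shared)))
    mat <- matrix(mat, nrow = length(shared))
    m <- if (cfg$replicate_combine == "mean_of_ratios") {
      rowMeans(mat)
    } else {
      pos <- mat[mat > 0]
      eps <- if (length(pos) > 0) min(pos) else 1
      2^rowMeans(log2(pmax(mat, eps)))
    }
    stats::setNames(m, shared)
  })
  list(mean_ratio = mean_ratio, barcodes = shared,
       n_replicates = vapply(ratios, length, integer(1)))
}

#' Log2 fold change of mean occupancy ratios against a baseline
#'
#' `log2fc = log2(mean_ratio / B_t)` where the per-timepoint baseline
#' `B_t` is the median mean-ratio over wild-type barcodes
#' (`wildtype_median`), over all entries (`all_median`), or 1 (`none`).
#' Zero ratios are floored to the smallest positive ratio in the table
#' before taking logs and flagged.
#'
#' @param mean_ratio Named numeric vector of mean ratios for one timepoint.
#' @param wildtype_barcodes Barcodes of the wild-type control population
#'   (required for `wildtype_median`).
#' @param cfg A [screen_config].
#' @return List with `log2fc` (named numeric), `baseline` (the value of
#'   `B_t`) and `floored` (logical vector flagging zero ratios).
#' @export
log2_fold_change <- function(mean_ratio, wildtype_barcodes = character(0),
                             cfg = screen_config()) {
  baseline <- switch(cfg$baseline_policy,
    wildtype_median = {
      wt <- mean_ratio[names(mean_ratio) %in% wildtype_barcodes]
      if (length(wt) == 0L) {
        stop("baseline_policy 'wildtype_median' but no wild-type barcodes survive")
      }
      midpoint_median(wt)
    },
    all_median = midpoint_median(mean_ratio),
    none = 1)
  if (baseline <= 0) stop("non-positive baseline")
  floored <- mean_ratio == 0
  if (any(floored)) {
    pos <- mean_ratio[mean_ratio > 0]
    if (length(pos) == 0L) stop("all mean ratios are zero")
    mean_ratio[floored] <- min(pos)
  }
  list(log2fc = log2(mean_ratio / baseline), baseline = baseline,
       floored = floored)
}

#' Classify mutants by log2 fold change at the two timepoints
#'
#' Four phenotype classes at threshold `tau` (all strict comparisons):
#' `down_both` (`fc40 < -tau` and `fc80 < -tau`: reduced occupancy at both
#' timepoints, the unstable-fork signature), `up_both` (`fc40 > tau` and
#' `fc80 > tau`: persistent stalling), `down_40_only` (`fc40 < -tau`,
#' `fc80 >= -tau`: slowed or delayed forks), `down_80_only`
#' (`|fc40| <= tau` and `fc80 < -tau`: fast forks that have moved past
#' the origin), and `other`. Classes are mutually exclusive and, with
#' `other`, exhaustive.
#'
#' @param log2fc_t40,log2fc_t80 Numeric vectors (finite), recycled to
#'   common length.
#' @param tau Threshold in log2 units (default 1.25).
#' @return Factor with levels `down_both`, `up_both`, `down_40_only`,
#'   `down_80_only`, `other`.
#' @export
classify_mutants <- function(log2fc_t40, log2fc_t80, tau = 1.25) {
  stopifnot(all(is.finite(log2fc_t40)), all(is.finite(log2fc_t80)))
  fc40 <- log2fc_t40
  fc80 <- log2fc_t80
  cls <- rep("other", max(length(fc40), length(fc80)))
  cls[fc40 < -tau & fc80 < -tau] <- "down_both"
  cls[fc40 > tau & fc80 > tau] <- "up_both"
  cls[fc40 < -tau & fc80 >= -tau] <- "down_40_only"
  cls[abs(fc40) <= tau & fc80 < -tau] <- "down_80_only"
  factor(cls, levels = HIT_CLASSES)
}

#' Replicate agreement of occupancy ratios
#'
#' Pearson correlation of log2 ratios over the barcodes shared by two
#' replicates (default), or Spearman correlation of the raw ratios.
#' Barcodes with a non-positive ratio in either replicate are dropped
#' for the log2 variant.
#'
#' @param rep1,rep2 Named ratio vectors for the same timepoint.
#' @param method `"pearson_log2"` (default) or `"spearman"`.
#' @return Correlation coefficient, or `NA` if undefined (fewer than 3
#'   shared barcodes or zero variance).
#' @export
replicate_correlation <- function(rep1, rep2,
                                  method = c("pearson_log2", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(names(rep1), names(rep2))
  x <- rep1[shared]; y <- rep2[shared]
  if (method == "pearson_log2") {
    keep <- x > 0 & y > 0
    x <- log2(x[keep]); y <- log2(y[keep])
  }
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  if (method == "pearson_log2") stats::cor(x, y)
  else stats::cor(x, y, method = "spearman")
}

#' Score a complete screen from per-sample barcode counts
#'
#' Runs the full quantification: per (timepoint, replicate) absence
#' filter on the input, median normalization of IP and input, IP/input
#' ratio; intersection of barcodes retained everywhere; replicate
#' averaging; log2 fold change against the configured baseline; and
#' four-class hit calling. Wild-type barcodes feed the baseline and are
#' never emitted as scored genes.
#'
#' @param counts_list List of `sample_counts`, each carrying a
#'   `sample_meta` with role, timepoint and replicate. Must contain an
#'   IP and an input sample for every (timepoint, replicate) pair, with
#'   at least one timepoint and one replicate.
#' @param map The [barcode_map].
#' @param cfg A [screen_config].
#' @return An object of class `score_table`: a data.frame with one row
#'   per scored mutant gene (columns `gene`, `strain_id`, `barcode`,
#'   `mean_ratio_t40`, `mean_ratio_t80`, `log2fc_t40`, `log2fc_t80`,
#'   `hit_class`, `n_replicates_used`, `floored_t40`, `floored_t80`),
#'   plus attributes `baseline` (per timepoint), `replicate_R` (per
#'   timepoint, between the first two replicates), `retained_n` (per
#'   sample pair), `wildtype_ratio` (per-timepoint wild-type mean
#'   ratios) and `config`.
#' @export
score_screen <- function(counts_list, map, cfg = screen_config()) {
  meta <- lapply(counts_list, function(x) {
    if (is.null(x$sample)) stop("every sample_counts needs sample_meta")
    x$sample
  })
  roles <- vapply(meta, `[[`, "", "role")
  tps <- vapply(meta, `[[`, integer(1), "timepoint")
  reps <- vapply(meta, `[[`, integer(1), "replicate")
  key <- paste(roles, tps, reps)
  if (anyDuplicated(key)) stop("duplicate (role, timepoint, replicate) sample")

  timepoints <- sort(unique(tps))
  replicates <- sort(unique(reps))

  ratios <- list()
  retained_n <- integer(0)
  for (t in timepoints) {
    ratios[[paste0("t", t)]] <- list()
    for (r in replicates) {
      ip <- which(roles == "IP" & tps == t & reps == r)
      inp <- which(roles == "input" & tps == t & reps == r)
      if (length(ip) != 1L || length(inp) != 1L) {
        stop(sprintf("need exactly one IP and one input sample for t=%d rep=%d",
                     t, r))
      }
      sc <- score_one_replicate(counts_list[[ip]], counts_list[[inp]], cfg)
      ratios[[paste0("t", t)]][[paste0("rep", r)]] <- sc$ratio
      retained_n[sprintf("t%d_rep%d", t, r)] <- length(sc$retained)
    }
  }

  merged <- merge_replicates(ratios, cfg)
  wt_barcodes <- map$barcode[map$strain_class == "wildtype"]

  fc <- lapply(merged$mean_ratio, log2_fold_change,
               wildtype_barcodes = wt_barcodes, cfg = cfg)

  ## replicate agreement between first two replicates, per timepoint
  repl_R <- vapply(ratios, function(tp) {
    if (length(tp) >= 2L) replicate_correlation(tp[[1]], tp[[2]])
    else NA_real_
  }, numeric(1))

  bcs <- merged$barcodes
  idx <- match(bcs, map$barcode)
  is_mut <- map$strain_class[idx] == "mutant"
  tn <- names(merged$mean_ratio)
  t40 <- tn[1]; t80 <- tn[length(tn)]

  tab <- data.frame(
    gene = map$gene[idx][is_mut],
    strain_id = map$strain_id[idx][is_mut],
    barcode = bcs[is_mut],
    mean_ratio_t40 = unname(merged$mean_ratio[[t40]][bcs[is_mut]]),
    mean_ratio_t80 = unname(merged$mean_ratio[[t80]][bcs[is_mut]]),
    log2fc_t40 = unname(fc[[t40]]$log2fc[bcs[is_mut]]),
    log2fc_t80 = unname(fc[[t80]]$log2fc[bcs[is_mut]]),
    stringsAsFactors = FALSE)
  tab$hit_class <- classify_mutants(tab$log2fc_t40, tab$log2fc_t80,
                                    cfg$hit_threshold)
  tab$n_replicates_used <- min(merged$n_replicates)
  tab$floored_t40 <- unname(fc[[t40]]$floored[bcs[is_mut]])
  tab$floored_t80 <- unname(fc[[t80]]$floored[bcs[is_mut]])

  attr(tab, "baseline") <- vapply(fc, `[[`, numeric(1), "baseline")
  attr(tab, "replicate_R") <- repl_R
  attr(tab, "retained_n") <- retained_n
  attr(tab, "wildtype_ratio") <- lapply(merged$mean_ratio, function(m)
    m[names(m) %in% wt_barcodes])
  attr(tab, "config") <- cfg
  class(tab) <- c("score_table", "data.frame")
  tab
}

#' Tally of hit classes in a score table
#'
#' @param score_table A `score_table` from [score_screen], or a factor of
#'   classes.
#' @return Named integer vector over the five classes.
#' @export
class_tally <- function(score_table) {
  cls <- if (is.factor(score_table)) score_table else score_table$hit_class
  tab <- table(factor(cls, levels = HIT_CLASSES))
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.score_table <- function(x, ...) {
  tal <- class_tally(x)
  cat(sprintf("score_table: %d mutants scored\n", nrow(x)))
  cat(sprintf("  %-14s %d\n", names(tal), tal), sep = "")
  R <- attr(x, "replicate_R")
  if (!is.null(R)) {
    cat("  replicate R:", paste(sprintf("%s = %.2f", names(R), R),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a score table to TSV
#'
#' @param score_table A `score_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_score_table <- function(score_table, path) {
  df <- as.data.frame(score_table)
  df$hit_class <- as.character(df$hit_class)
  write_tsv(df, path)
}
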