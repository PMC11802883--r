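## End-to-end pipeline driver: read a config, count every sample, score
## the screen, and write the score table, scatter table, QC and a run
## manifest sufficient to re-run the identical analysis.

#' Run the screen-scoring pipeline from a config file
#'
#' The config (YAML) names the inputs and thresholds:
#'
#' ```yaml
#' barcode_map: path/to/barcode_map.tsv
#' sample_sheet: path/to/sample_sheet.tsv   # sample_id fastq_path role timepoint replicate
#' out_dir: path/to/output
#' absence_fraction: 2.5e-5
#' hit_threshold: 1.25
#' baseline_policy: wildtype_median
#' replicate_combine: mean_of_ratios
#' policy: exact            # barcode matching
#' anchor: CGTACGCTGC       # read structure
#' barcode_length: 20
#' anchor_max_mismatch: 0
#' ```
#'
#' Writes under `out_dir`: `score_table.tsv`, `scatter.tsv` (gene,
#' log2fc_t40, log2fc_t80, hit_class — the two-timepoint scatter),
#' `qc.tsv` (per-sample totals and assignment rates), `counts_<sample>.tsv`
#' per sample, and `run_manifest.yaml` (config snapshot, input checksums,
#' per-sample QC, retained-barcode counts, baselines, class tallies,
#' package version). The run is deterministic given the inputs; class
#' tallies are printed on completion.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param quiet Suppress the printed tallies (default FALSE).
#' @return The `score_table`, invisibly, with attribute `manifest`.
#' @export
run_screen_pipeline <- function(config, quiet = FALSE) {
  cfg_in <- if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    yaml::read_yaml(config)
  } else config

  need <- c("barcode_map", "sample_sheet", "out_dir")
  missing <- setdiff(need, names(cfg_in))
  if (length(missing) > 0L) {
    stop(sprintf("config is missing required key(s): %s",
                 paste(missing, collapse = ", ")))
  }

  cfg <- screen_config(
    absence_fraction = cfg_in$absence_fraction %||% 2.5e-5,
    hit_threshold = cfg_in$hit_threshold %||% 1.25,
    baseline_policy = cfg_in$baseline_policy %||% "wildtype_median",
    replicate_combine = cfg_in$replicate_combine %||% "mean_of_ratios")
  strc <- read_structure(
    anchor = cfg_in$anchor %||% "CGTACGCTGC",
    barcode_length = cfg_in$barcode_length %||% 20L,
    anchor_max_mismatch = cfg_in$anchor_max_mismatch %||% 0L)
  policy <- cfg_in$policy %||% "exact"

  map <- load_barcode_map(cfg_in$barcode_map)
  sheet <- read_tsv_strict(cfg_in$sample_sheet,
                           c("sample_id", "fastq_path", "role", "timepoint",
                             "replicate"), what = "sample sheet")
  ## fastq paths in the sheet are relative to the sheet's directory
  ## unless absolute
  base <- dirname(cfg_in$sample_sheet)
  abs_path <- ifelse(grepl("^(/|[A-Za-z]:)", sheet$fastq_path),
                     sheet$fastq_path, file.path(base, sheet$fastq_path))

  out_dir <- cfg_in$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  counts_list <- vector("list", nrow(sheet))
  qc <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    meta <- sample_meta(sheet$sample_id[i], sheet$role[i],
                        as.integer(sheet$timepoint[i]),
                        as.integer(sheet$replicate[i]))
    counts_list[[i]] <- count_barcodes(abs_path[i], map, strc,
                                       policy = policy, sample = meta)
    write_counts(counts_list[[i]], map,
                 file.path(out_dir, sprintf("counts_%s.tsv",
                                            sheet$sample_id[i])))
    qc[[i]] <- data.frame(
      sample_id = sheet$sample_id[i],
      total = counts_list[[i]]$total_reads,
      assigned = counts_list[[i]]$assigned_reads,
      unassigned = counts_list[[i]]$unassigned_reads,
      assignment_rate = counts_list[[i]]$assigned_reads /
        max(1L, counts_list[[i]]$total_reads),
      stringsAsFactors = FALSE)
  }
  qc <- do.call(rbind, qc)
  write_tsv(qc, file.path(out_dir, "qc.tsv"))

  st <- score_screen(counts_list, map, cfg)
  write_score_table(st, file.path(out_dir, "score_table.tsv"))
  scatter <- data.frame(gene = st$gene, log2fc_t40 = st$log2fc_t40,
                        log2fc_t80 = st$log2fc_t80,
                        hit_class = as.character(st$hit_class),
                        stringsAsFactors = FALSE)
  write_tsv(scatter, file.path(out_dir, "scatter.tsv"))

  tallies <- class_tally(st)
  manifest <- list(
    config = list(absence_fraction = cfg$absence_fraction,
                  hit_threshold = cfg$hit_threshold,
                  baseline_policy = cfg$baseline_policy,
                  replicate_combine = cfg$replicate_combine,
                  policy = policy, anchor = strc$anchor,
                  barcode_length = strc$barcode_length,
                  anchor_max_mismatch = strc$anchor_max_mismatch,
                  barcode_map = cfg_in$barcode_map,
                  sample_sheet = cfg_in$sample_sheet,
                  out_dir = out_dir),
    input_md5 = as.list(tools::md5sum(c(cfg_in$barcode_map,
                                        cfg_in$sample_sheet, abs_path))),
    qc = split(qc, seq_len(nrow(qc))),
    retained_barcodes = as.list(attr(st, "retained_n")),
    baseline = as.list(attr(st, "baseline")),
    replicate_R = as.list(attr(st, "replicate_R")),
    class_tally = as.list(tallies),
    n_scored = nrow(st),
    tool_version = as.character(utils::packageVersion("repliid")))
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))

  if (!quiet) {
    message(sprintf("scored %d mutants", nrow(st)))
    message(paste(sprintf("%s: %d", names(tallies), tallies),
                  collapse = "  "))
  }
  attr(st, "manifest") <- manifest
  invisible(st)
}
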