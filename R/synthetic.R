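## Synthetic screens with known ground truth: barcode libraries, pooled
## IP/input FASTQ files and colony plates, so every pipeline stage can be
## validated end to end without external data.

#' Parameters of the synthetic screen generator
#'
#' The generator emulates a pooled origin-occupancy screen: a library of
#' barcoded deletion mutants plus barcoded wild-type controls, log-normal
#' strain abundances in the pool, per-class occupancy effects acting on
#' IP recovery at the two timepoints, log-normal per-replicate occupancy
#' noise, multinomial read sampling at a chosen depth and i.i.d. per-base
#' substitution errors.
#'
#' @param n_mutants Number of barcoded mutants (default 4500).
#' @param n_wildtypes Number of barcoded wild-type controls (default
#'   1100).
#' @param barcode_length Barcode length in bp (default 20).
#' @param min_pairwise_hamming Minimum pairwise Hamming distance between
#'   library barcodes (default 3; screen barcodes are designed well
#'   separated).
#' @param abundance_log_sd SD of strain abundance on the natural-log
#'   scale (default 0.5).
#' @param class_proportions Named numeric vector of mutant-class
#'   proportions over `down_both`, `up_both`, `down_40_only`,
#'   `down_80_only`; the remainder is `other` with effect 0. Defaults
#'   echo the hit structure of a typical screen (15%/4%/5%/5%).
#' @param class_effects Named list mapping each class to its
#'   `c(t40, t80)` occupancy effect in log2 units.
#' @param read_depth Reads per sample (default 2e6).
#' @param base_error_rate Per-base substitution error probability
#'   (default 0.002); must be < 0.25.
#' @param replicate_noise_sd SD of the per-(strain, replicate) occupancy
#'   noise on the natural-log scale (default 0.1).
#' @param n_replicates Number of replicate screens (default 2).
#' @param timepoints Sampling timepoints in minutes (default c(40, 80)).
#' @param structure A [read_structure] defining the emitted amplicon
#'   layout.
#' @param filler 3' filler sequence appended after the barcode.
#' @param seed Default RNG seed used by the generator functions.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_mutants = 4500, n_wildtypes = 1100,
                              barcode_length = 20,
                              min_pairwise_hamming = 3,
                              abundance_log_sd = 0.5,
                              class_proportions = c(down_both = 0.15,
                                                    up_both = 0.04,
                                                    down_40_only = 0.05,
                                                    down_80_only = 0.05),
                              class_effects = list(
                                down_both = c(-2, -2),
                                up_both = c(2, 2),
                                down_40_only = c(-2, 0),
                                down_80_only = c(0, -2),
                                other = c(0, 0)),
                              read_depth = 2e6,
                              base_error_rate = 0.002,
                              replicate_noise_sd = 0.1,
                              n_replicates = 2,
                              timepoints = c(40L, 80L),
                              structure = read_structure(
                                barcode_length = barcode_length),
                              filler = "ACGTC",
                              seed = 1L) {
  stopifnot(n_mutants >= 0, n_wildtypes >= 0, n_mutants + n_wildtypes > 0,
            read_depth > 0, base_error_rate >= 0, base_error_rate < 0.25,
            abundance_log_sd >= 0, replicate_noise_sd >= 0,
            length(timepoints) == 2L)
  if (sum(class_proportions) > 1 + 1e-12) {
    stop("class proportions must sum to <= 1")
  }
  if (structure$barcode_length != barcode_length) {
    stop("structure barcode_length must equal barcode_length")
  }
  out <- list(n_mutants = as.integer(n_mutants),
                 n_wildtypes = as.integer(n_wildtypes),
                 barcode_length = as.integer(barcode_length),
                 min_pairwise_hamming = as.integer(min_pairwise_hamming),
                 abundance_log_sd = abundance_log_sd,
                 class_proportions = class_proportions,
                 class_effects = class_effects,
                 read_depth = read_depth,
                 base_error_rate = base_error_rate,
                 replicate_noise_sd = replicate_noise_sd,
                 n_replicates = as.integer(n_replicates),
                 timepoints = as.integer(timepoints),
                 structure = structure,
                 filler = toupper(filler),
                 seed = as.integer(seed))
  class(out) <- "simulation_params"
  out
}

## Draw n distinct barcodes of length L, rejecting candidates within
## min_dist of an accepted one (vectorised integer-matrix distances).
draw_barcodes <- function(n, L, min_dist, max_tries = 50L) {
  accepted <- matrix(integer(0), ncol = L)
  tries <- 0L
  while (nrow(accepted) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place requested barcodes at the requested minimum distance; increase barcode_length")
    }
    need <- n - nrow(accepted)
    batch <- matrix(utf8ToInt(paste(sample(DNA_BASES, need * L,
                                           replace = TRUE),
                                    collapse = "")),
                    ncol = L, byrow = TRUE)
    for (i in seq_len(nrow(batch))) {
      cand <- batch[i, ]
      if (min_dist <= 0L) {
        if (nrow(accepted) == 0L ||
            !any(row_hamming(accepted, cand) == 0L)) {
          accepted <- rbind(accepted, cand)
        }
      } else if (nrow(accepted) == 0L ||
                 all(row_hamming(accepted, cand) >= min_dist)) {
        accepted <- rbind(accepted, cand)
      }
      if (nrow(accepted) == n) break
    }
  }
  apply(accepted, 1L, function(r) intToUtf8(r))
}

#' Generate a barcoded strain library with ground truth
#'
#' Draws well-separated barcodes, assigns mutant classes by the stated
#' proportions with the per-class occupancy effects, and draws log-normal
#' strain abundances. Wild-type strains share the gene label `"WT"` and
#' always have occupancy multiplier 1. Deterministic given the seed.
#'
#' @param params A [simulation_params].
#' @param seed RNG seed (default `params$seed`).
#' @return List with `map` (a [barcode_map]) and `truth` (data.frame:
#'   `strain_id`, `gene`, `strain_class`, `abundance`, `m_t40`, `m_t80`,
#'   `true_class`).
#' @export
generate_barcode_library <- function(params, seed = params$seed) {
  set.seed(seed)
  n <- params$n_mutants + params$n_wildtypes
  if (4^params$barcode_length < 4 * n) {
    stop("barcode space too small for requested library")
  }
  bcs <- draw_barcodes(n, params$barcode_length, params$min_pairwise_hamming)

  strain_id <- sprintf("strain_%05d", seq_len(n))
  is_mut <- seq_len(n) <= params$n_mutants
  gene <- ifelse(is_mut, sprintf("GENE%05d", cumsum(is_mut)), "WT")
  strain_class <- ifelse(is_mut, "mutant", "wildtype")
  map <- barcode_map(bcs, strain_id, gene, strain_class)

  ## mutant classes by proportion; remainder (and all wild types) = other
  props <- params$class_proportions
  n_per <- floor(props * params$n_mutants)
  cls <- rep("other", n)
  if (params$n_mutants > 0L && sum(n_per) > 0L) {
    assigned <- sample(seq_len(params$n_mutants), sum(n_per))
    cls[assigned] <- rep(names(n_per), n_per)
  }

  eff <- do.call(rbind, params$class_effects[cls])
  m_t40 <- 2^eff[, 1]
  m_t80 <- 2^eff[, 2]
  m_t40[!is_mut] <- 1
  m_t80[!is_mut] <- 1

  abundance <- exp(stats::rnorm(n, 0, params$abundance_log_sd))

  ## the truth class is defined by the injected effects themselves (at
  ## the standard threshold), so zero-effect configurations are "other"
  true_class <- as.character(classify_mutants(log2(m_t40), log2(m_t80)))
  true_class[!is_mut] <- "other"

  truth <- data.frame(strain_id = strain_id, gene = gene,
                      strain_class = strain_class,
                      abundance = abundance,
                      m_t40 = m_t40, m_t80 = m_t80,
                      true_class = true_class, stringsAsFactors = FALSE)
  list(map = map, truth = truth)
}

## Inject i.i.d. substitution errors into a vector of equal-length reads.
inject_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  len <- nchar(reads[1])
  k <- stats::rbinom(length(reads), len, rate)
  hit <- which(k > 0L)
  if (length(hit) == 0L) return(reads)
  ## distinct error positions per read
  pos_list <- lapply(k[hit], function(ki) sample.int(len, ki))
  idx <- rep(hit, k[hit])
  pos <- unlist(pos_list)
  cur <- substr(rep(reads[idx], 1L), pos, pos)
  ## substitute with one of the three other bases
  alt <- matrix(c("C", "G", "T",   # A ->
                  "A", "G", "T",   # C ->
                  "A", "C", "T",   # G ->
                  "A", "C", "G"),  # T ->
                nrow = 4, byrow = TRUE,
                dimnames = list(DNA_BASES, NULL))
  newb <- alt[cbind(match(cur, DNA_BASES), sample.int(3L, length(pos),
                                                      replace = TRUE))]
  ## apply events in passes so each pass touches each read at most once
  pass <- stats::ave(seq_along(idx), idx, FUN = seq_along)
  for (p in seq_len(max(pass))) {
    sel <- pass == p
    x <- reads[idx[sel]]
    substr(x, pos[sel], pos[sel]) <- newb[sel]
    reads[idx[sel]] <- x
  }
  reads
}

write_fastq <- function(seqs, path, gzip = TRUE) {
  n <- length(seqs)
  qual <- strrep("I", nchar(seqs))
  heads <- paste0("@read", seq_len(n))
  con <- if (gzip) gzfile(path, "wb", compression = 1L) else file(path, "wb")
  on.exit(close(con))
  writeLines(c(rbind(heads, seqs, rep("+", n), qual)), con)
  invisible(path)
}

#' Simulate a pooled screen as FASTQ files
#'
#' For every sample (IP and input at each timepoint, each replicate),
#' draws barcode read counts from a multinomial at the configured depth
#' and emits reads `anchor + barcode + filler` with i.i.d. substitution
#' errors. Input expected proportions are proportional to strain
#' abundance; IP proportions are additionally scaled by the strain's
#' occupancy multiplier at that timepoint and by per-(strain, replicate)
#' log-normal noise shared across timepoints. Deterministic given the
#' seed.
#'
#' @param map A [barcode_map] from [generate_barcode_library].
#' @param truth The matching truth data.frame.
#' @param params A [simulation_params].
#' @param out_dir Output directory (created if missing).
#' @param seed RNG seed (default `params$seed`).
#' @param gzip Whether to gzip the FASTQ files (default TRUE).
#' @return List with `sample_sheet` (data.frame: sample_id, fastq_path,
#'   role, timepoint, replicate), and the paths of the sample sheet,
#'   barcode map, truth table and manifest written under `out_dir`.
#' @export
simulate_screen <- function(map, truth, params, out_dir,
                            seed = params$seed, gzip = TRUE) {
  stopifnot(identical(map$strain_id, truth$strain_id))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  n <- nrow(map)
  a <- truth$abundance
  mult <- list(truth$m_t40, truth$m_t80)
  names(mult) <- paste0("t", params$timepoints)

  ## per-(strain, replicate) occupancy noise, shared across timepoints
  eps <- matrix(exp(stats::rnorm(n * params$n_replicates, 0,
                                 params$replicate_noise_sd)),
                nrow = n)

  anchor <- params$structure$anchor
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  sheet <- list()
  for (r in seq_len(params$n_replicates)) {
    for (t in params$timepoints) {
      for (role in c("input", "IP")) {
        prob <- if (role == "input") a
                else a * mult[[paste0("t", t)]] * eps[, r]
        counts <- as.integer(stats::rmultinom(1, params$read_depth,
                                              prob / sum(prob)))
        reads <- paste0(anchor, rep(map$barcode, counts), params$filler)
        reads <- inject_errors(reads, params$base_error_rate)
        sid <- sprintf("%s_t%d_rep%d", role, t, r)
        path <- file.path(out_dir, paste0(sid, ext))
        write_fastq(reads, path, gzip = gzip)
        sheet[[sid]] <- data.frame(sample_id = sid, fastq_path = path,
                                   role = role, timepoint = t,
                                   replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  sample_sheet <- do.call(rbind, sheet)
  rownames(sample_sheet) <- NULL

  sheet_path <- file.path(out_dir, "sample_sheet.tsv")
  ## on disk, fastq paths are stored relative to the sheet's directory
  sheet_disk <- sample_sheet
  sheet_disk$fastq_path <- basename(sheet_disk$fastq_path)
  write_tsv(sheet_disk, sheet_path)
  map_path <- file.path(out_dir, "barcode_map.tsv")
  write_barcode_map(map, map_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  write_tsv(truth, truth_path)
  manifest_path <- file.path(out_dir, "sim_manifest.yaml")
  yaml::write_yaml(list(
    n_mutants = params$n_mutants, n_wildtypes = params$n_wildtypes,
    barcode_length = params$barcode_length,
    min_pairwise_hamming = params$min_pairwise_hamming,
    abundance_log_sd = params$abundance_log_sd,
    class_proportions = as.list(params$class_proportions),
    class_effects = lapply(params$class_effects, as.numeric),
    read_depth = params$read_depth,
    base_error_rate = params$base_error_rate,
    replicate_noise_sd = params$replicate_noise_sd,
    n_replicates = params$n_replicates,
    timepoints = params$timepoints,
    anchor = anchor, filler = params$filler, seed = seed), manifest_path)

  list(sample_sheet = sample_sheet, sample_sheet_path = sheet_path,
       map_path = map_path, truth_path = truth_path,
       manifest_path = manifest_path)
}

#' Simulate a pair of suppressor-screen colony plates
#'
#' Control colony sizes are log-normal; treated sizes equal the control
#' size times the suppression effect (for true suppressors; 1 otherwise)
#' times log-normal noise. Wells are laid out on a near-square grid.
#' Deterministic given the seed.
#'
#' @param n_strains Number of strains (>= 4).
#' @param suppressor_fraction Fraction of strains that are true
#'   suppressors.
#' @param effect Multiplicative growth advantage of true suppressors on
#'   the treated plate.
#' @param noise_sd SD of the treated-plate noise on the natural-log
#'   scale.
#' @param seed RNG seed.
#' @param size_meanlog,size_sdlog Log-normal parameters of control colony
#'   sizes (defaults log(200) and 0.25, colony areas in arbitrary units).
#' @return List with `control` and `treated` ([colony_plate]s) and
#'   `truth` (data.frame: strain_id, is_suppressor).
#' @export
simulate_colony_plates <- function(n_strains, suppressor_fraction = 0.1,
                                   effect = 2, noise_sd = 0.1, seed = 1L,
                                   size_meanlog = log(200),
                                   size_sdlog = 0.25) {
  stopifnot(n_strains >= 4)
  set.seed(seed)
  strain_id <- sprintf("strain_%05d", seq_len(n_strains))
  is_sup <- rep(FALSE, n_strains)
  n_sup <- round(suppressor_fraction * n_strains)
  if (n_sup > 0L) is_sup[sample.int(n_strains, n_sup)] <- TRUE

  ctrl_size <- stats::rlnorm(n_strains, size_meanlog, size_sdlog)
  trt_size <- ctrl_size * ifelse(is_sup, effect, 1) *
    exp(stats::rnorm(n_strains, 0, noise_sd))

  ncol_grid <- ceiling(sqrt(n_strains))
  row <- (seq_len(n_strains) - 1L) %/% ncol_grid + 1L
  col <- (seq_len(n_strains) - 1L) %% ncol_grid + 1L

  list(control = colony_plate("plate1_ypd", "control", row, col,
                              strain_id, ctrl_size),
       treated = colony_plate("plate1_hu", "treated", row, col,
                              strain_id, trt_size),
       truth = data.frame(strain_id = strain_id, is_suppressor = is_sup,
                          stringsAsFactors = FALSE))
}

#' Compare recovered hit classes with simulated truth
#'
#' @param score_table A `score_table` from [score_screen].
#' @param truth Truth data.frame from [generate_barcode_library] (mutant
#'   rows are used; identifiers must match).
#' @param tau Hit threshold used when interpreting truth classes (kept
#'   for the caller's record; truth classes are as assigned by the
#'   generator).
#' @return List with `confusion` (integer matrix, rows = true class,
#'   columns = called class), `sensitivity` and `precision` (named per
#'   class; precision `NA` where a class was never called), and
#'   `n_scored`.
#' @export
evaluate_recovery <- function(score_table, truth, tau = 1.25) {
  truth_mut <- truth[truth$strain_class == "mutant", , drop = FALSE]
  m <- match(score_table$gene, truth_mut$gene)
  if (anyNA(m)) {
    stop(sprintf("scored gene absent from truth: %s",
                 score_table$gene[which(is.na(m))[1]]))
  }
  true_cls <- factor(truth_mut$true_class[m], levels = HIT_CLASSES)
  called <- factor(score_table$hit_class, levels = HIT_CLASSES)
  confusion <- table(true = true_cls, called = called)

  diagv <- diag(confusion)
  true_n <- rowSums(confusion)
  called_n <- colSums(confusion)
  sensitivity <- ifelse(true_n > 0, diagv / true_n, NA_real_)
  precision <- ifelse(called_n > 0, diagv / called_n, NA_real_)

  list(confusion = unclass(confusion),
       sensitivity = stats::setNames(as.numeric(sensitivity), HIT_CLASSES),
       precision = stats::setNames(as.numeric(precision), HIT_CLASSES),
       n_scored = nrow(score_table))
}

#' Simulate, count and score a synthetic screen end to end
#'
#' Convenience wrapper: generates the library, writes the FASTQ samples,
#' counts barcodes in every sample and scores the screen. Intermediate
#' FASTQ files are written under `out_dir`.
#'
#' @param params A [simulation_params].
#' @param out_dir Output directory (default a fresh temporary directory).
#' @param cfg A [screen_config].
#' @param policy Barcode matching policy for counting.
#' @param gzip Whether FASTQ files are gzipped.
#' @param keep_fastq Keep the FASTQ files after counting (default FALSE:
#'   they are deleted to save disk).
#' @return List with `score_table`, `truth`, `map`, `qc` (per-sample QC
#'   data.frame) and `out_dir`.
#' @export
run_synthetic_screen <- function(params, out_dir = tempfile("synscreen"),
                                 cfg = screen_config(),
                                 policy = "exact", gzip = FALSE,
                                 keep_fastq = FALSE) {
  lib <- generate_barcode_library(params)
  sim <- simulate_screen(lib$map, lib$truth, params, out_dir, gzip = gzip)
  counts_list <- vector("list", nrow(sim$sample_sheet))
  qc <- vector("list", nrow(sim$sample_sheet))
  for (i in seq_len(nrow(sim$sample_sheet))) {
    s <- sim$sample_sheet[i, ]
    meta <- sample_meta(s$sample_id, s$role, s$timepoint, s$replicate)
    counts_list[[i]] <- count_barcodes(s$fastq_path, lib$map,
                                       params$structure, policy = policy,
                                       sample = meta)
    qc[[i]] <- data.frame(
      sample_id = s$sample_id,
      total = counts_list[[i]]$total_reads,
      assigned = counts_list[[i]]$assigned_reads,
      unassigned = counts_list[[i]]$unassigned_reads,
      assignment_rate = counts_list[[i]]$assigned_reads /
        max(1L, counts_list[[i]]$total_reads),
      stringsAsFactors = FALSE)
    if (!keep_fastq) unlink(s$fastq_path)
  }
  st <- score_screen(counts_list, lib$map, cfg)
  list(score_table = st, truth = lib$truth, map = lib$map,
       qc = do.call(rbind, qc), out_dir = out_dir)
}
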