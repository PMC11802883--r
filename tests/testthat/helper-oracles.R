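## Independent oracles and small fixture builders used across tests.

## Naive per-read barcode assignment: enumerates every anchor position in
## the window and, for matching, every map barcode. Deliberately written
## as plain loops, independent of the package's vectorised path.
naive_assign <- function(read, anchor, L, max_mm, wstart, wend_excl,
                         map_barcodes, policy) {
  alen <- nchar(anchor)
  pos <- NA
  if (alen == 0L) {
    pos <- wstart + 1L
  } else {
    for (p0 in wstart:(wend_excl - 1L)) {
      if (nchar(read) < p0 + alen) next
      mm <- 0L
      for (i in seq_len(alen)) {
        if (substr(read, p0 + i, p0 + i) != substr(anchor, i, i)) mm <- mm + 1L
      }
      if (mm <= max_mm) { pos <- p0 + alen + 1L; break }
    }
  }
  if (is.na(pos)) return(list(barcode = NA, reason = "no_anchor"))
  if (nchar(read) < pos + L - 1L) return(list(barcode = NA, reason = "short_read"))
  cand <- substr(read, pos, pos + L - 1L)
  for (b in map_barcodes) if (b == cand) return(list(barcode = b, reason = NA))
  if (policy == "exact") return(list(barcode = NA, reason = "unknown_barcode"))
  within1 <- character(0)
  for (b in map_barcodes) {
    d <- 0L
    for (i in seq_len(L)) {
      if (substr(b, i, i) != substr(cand, i, i)) d <- d + 1L
    }
    if (d == 1L) within1 <- c(within1, b)
  }
  if (length(within1) == 1L) list(barcode = within1, reason = NA)
  else if (length(within1) > 1L) list(barcode = NA, reason = "ambiguous_correction")
  else list(barcode = NA, reason = "unknown_barcode")
}

naive_count <- function(reads, anchor, L, max_mm, wstart, wend_excl,
                        map_barcodes, policy) {
  counts <- setNames(integer(length(map_barcodes)), map_barcodes)
  unassigned <- 0L
  for (r in reads) {
    a <- naive_assign(r, anchor, L, max_mm, wstart, wend_excl,
                      map_barcodes, policy)
    if (is.na(a$barcode[1])) unassigned <- unassigned + 1L
    else counts[a$barcode] <- counts[a$barcode] + 1L
  }
  list(counts = counts, unassigned = unassigned)
}

## Random DNA sequences.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

## Brute-force two-sided hypergeometric p via lchoose, enumerating the
## full support of the 2x2 table with fixed margins.
brute_fisher_two_sided <- function(k, n, K, N) {
  supp <- max(0L, n + K - N):min(n, K)
  lp <- lchoose(K, supp) + lchoose(N - K, n - supp) - lchoose(N, n)
  pmf <- exp(lp)
  p_obs <- pmf[match(k, supp)]
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

## A tiny 3-sample counts fixture with a known map, built in code.
toy_map <- function() {
  barcode_map(
    barcode = c("ACGTACGTACGTACGTACGT",
                "TTTTACGTACGTACGTACGT",
                "GGGGACGTACGTACGTACGT",
                "CCCCACGTACGTACGTACGT"),
    strain_id = c("s1", "s2", "s3", "wt1"),
    gene = c("GENE1", "GENE2", "GENE3", "WT"),
    strain_class = c("mutant", "mutant", "mutant", "wildtype"))
}

## Build a sample_counts object directly from a named count vector.
make_counts <- function(counts, map, role = "input", timepoint = 40,
                        replicate = 1, total = sum(counts),
                        id = paste0(role, "_t", timepoint, "_r", replicate)) {
  full <- setNames(integer(nrow(map)), map$barcode)
  full[names(counts)] <- as.integer(counts)
  out <- list(sample = sample_meta(id, role, timepoint, replicate),
              counts = full, total_reads = as.integer(total),
              assigned_reads = sum(full),
              unassigned_reads = as.integer(total) - sum(full),
              unassigned_by_reason = NULL)
  class(out) <- "sample_counts"
  out
}

## Standard-scenario simulation parameters used by the recovery and null
## checks: 500 mutants + 100 wild types, 10% reduced-occupancy strains at
## log2 effect -2 (both timepoints), 5% increased at +2, abundance log-SD
## 0.5, replicate log-noise 0.1, base error 0.002, 2e6 reads/sample,
## 2 replicates.
standard_scenario <- function(seed, null_effects = FALSE) {
  effects <- if (null_effects) {
    list(down_both = c(0, 0), up_both = c(0, 0),
         down_40_only = c(0, 0), down_80_only = c(0, 0), other = c(0, 0))
  } else {
    list(down_both = c(-2, -2), up_both = c(2, 2),
         down_40_only = c(-2, 0), down_80_only = c(0, -2), other = c(0, 0))
  }
  simulation_params(
    n_mutants = 500, n_wildtypes = 100,
    class_proportions = c(down_both = 0.10, up_both = 0.05,
                          down_40_only = 0, down_80_only = 0),
    class_effects = effects,
    abundance_log_sd = 0.5, replicate_noise_sd = 0.1,
    base_error_rate = 0.002, read_depth = 2e6, n_replicates = 2,
    seed = seed)
}

## One-row colony plate with sequential strain ids.
plate_of <- function(sizes, condition = "control", id = "p1") {
  n <- length(sizes)
  colony_plate(id, condition, row = rep(1L, n), column = seq_len(n),
               strain_id = sprintf("s%02d", seq_len(n)), colony_size = sizes)
}
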