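#!/usr/bin/env Rscript

## Step 4: overlap enrichment. First the desk-scale check on the
## published 2x2 counts for the G1-arrest annotation (21 of 423 hits vs
## 152 of 4342 genes), then the same computation on the simulated
## screen's down_both hit list against an annotation set drawn from the
## simulation truth.

library(repliid)

## published counts: 21/423 hits annotated, 152/4342 genome-wide
ov <- overlap_result(k = 21, n = 423, K = 152, N = 4342)
print(ov)

## simulated screen: annotate all true down_both genes plus a random 3%
## background, then test the recovered hit list against it
st <- read.delim("results/screen/score_table.tsv", stringsAsFactors = FALSE)
truth <- read.delim("results/simulated_screen/truth.tsv",
                    stringsAsFactors = FALSE)
truth <- truth[truth$strain_class == "mutant", ]

set.seed(2024)
universe <- st$gene
annotation <- union(truth$gene[truth$true_class == "down_both"],
                    sample(universe, round(0.03 * length(universe))))
hits <- st$gene[st$hit_class == "down_both"]
ov_sim <- overlap_enrichment(hits, annotation, universe)
print(ov_sim)

dir.create("results/overlap", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(
  comparison = c("published_counts", "simulated_screen"),
  k = c(ov$k, ov_sim$k), n = c(ov$n, ov_sim$n),
  K = c(ov$K, ov_sim$K), N = c(ov$N, ov_sim$N),
  pct_hits = c(ov$pct_hits, ov_sim$pct_hits),
  pct_universe = c(ov$pct_universe, ov_sim$pct_universe),
  fisher_p = c(ov$fisher_p, ov_sim$fisher_p),
  odds_ratio = c(ov$odds_ratio, ov_sim$odds_ratio)),
  "results/overlap/overlap.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("wrote results/overlap/overlap.tsv\n")
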