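#!/usr/bin/env Rscript

## Step 3: compare the recovered hit classes with the simulation's
## ground truth: per-class sensitivity/precision and the confusion
## matrix, written to results/recovery/.

library(repliid)

st <- read.delim("results/screen/score_table.tsv",
                 stringsAsFactors = FALSE)
st$hit_class <- factor(st$hit_class,
                       levels = c("down_both", "up_both", "down_40_only",
                                  "down_80_only", "other"))
truth <- read.delim("results/simulated_screen/truth.tsv",
                    stringsAsFactors = FALSE)

ev <- evaluate_recovery(st, truth, tau = 1.25)
cat("confusion matrix (rows = truth, columns = called):\n")
print(ev$confusion)
cat("\nper-class sensitivity:\n"); print(round(ev$sensitivity, 3))
cat("per-class precision:\n"); print(round(ev$precision, 3))

dir.create("results/recovery", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(class = names(ev$sensitivity),
                       sensitivity = ev$sensitivity,
                       precision = ev$precision),
            "results/recovery/metrics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(as.data.frame.matrix(ev$confusion),
            "results/recovery/confusion.tsv", sep = "\t", quote = FALSE)
cat("\nwrote results/recovery/\n")
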