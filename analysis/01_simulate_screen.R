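#!/usr/bin/env Rscript

## Step 1: simulate a pooled origin-occupancy screen with known ground
## truth. A scaled-down pool (500 mutants + 100 wild-type controls,
## 5e5 reads/sample) keeps this demonstration quick; the generator's
## defaults correspond to a full-size pool (~4500 mutants + ~1100 wild
## types, 2e6 reads/sample).

library(repliid)

out_dir <- "results/simulated_screen"

params <- simulation_params(
  n_mutants = 500, n_wildtypes = 100,
  class_proportions = c(down_both = 0.10, up_both = 0.05,
                        down_40_only = 0.03, down_80_only = 0.03),
  read_depth = 5e5, n_replicates = 2, seed = 2024)

lib <- generate_barcode_library(params)
cat(sprintf("library: %d mutants, %d wild types, barcode length %d\n",
            sum(lib$map$strain_class == "mutant"),
            sum(lib$map$strain_class == "wildtype"),
            attr(lib$map, "barcode_length")))
cat("injected classes:\n")
print(table(lib$truth$true_class[lib$truth$strain_class == "mutant"]))

sim <- simulate_screen(lib$map, lib$truth, params, out_dir)
cat(sprintf("wrote %d FASTQ samples, sample sheet, map and truth under %s\n",
            nrow(sim$sample_sheet), out_dir))
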