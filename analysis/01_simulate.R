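#!/usr/bin/env Rscript
# Stage 1: generate the synthetic anagen/catagen study dataset.
#
# Emulates the 3-vs-3 two-phase skin design with realistic log-normal
# biological noise (log2 sd 0.5) and planted ground truth: DE features,
# high-correlation lncRNA-mRNA pairs, cis neighbours in the 10/100 kb
# windows, and five shared-8mer ceRNA triads. The manifest written
# alongside the data is the oracle used by the later stages' recovery
# summaries.

suppressPackageStartupMessages(library(cernet))

data_dir <- "results/analysis/data"
cfg <- simulation_config(seed = 20L)   # study conditions: noise_sd = 0.5
sim <- simulate_dataset(cfg, out_dir = data_dir)

man <- sim$manifest
cat("Synthetic dataset written to", data_dir, "\n")
cat(sprintf("  transcripts: %d (%d coding, %d known lncRNA, %d novel lncRNA, %d decoys)\n",
            nrow(man$features), sum(man$features$class == "coding"),
            sum(man$features$class == "known_lnc"),
            sum(man$features$class == "novel_lnc"),
            sum(grepl("^decoy", man$features$class))))
cat(sprintf("  miRNA catalog: %d\n", nrow(man$mirnas)))
cat(sprintf("  planted DE: %d transcripts, %d miRNAs\n",
            sum(man$features$de), sum(man$mirnas$de)))
cat(sprintf("  planted trans pairs: %d, cis pairs: %d, ceRNA triads: %d\n",
            nrow(man$trans_pairs), nrow(man$cis_pairs), nrow(man$triads)))
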