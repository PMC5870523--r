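#!/usr/bin/env Rscript
# Stage 6: over-representation analysis of DE coding genes.
#
# Hypergeometric upper-tail enrichment of DE genes against the expressed
# background (max FPKM >= 0.5), BH-corrected; terms with corrected
# p < 0.05 are called enriched.

suppressPackageStartupMessages(library(cernet))

data_dir <- "results/analysis/data"
out_dir <- "results/analysis"
design <- read_design(file.path(data_dir, "design.tsv"))
coding_ids <- readLines(file.path(data_dir, "coding_ids.txt"))
fpkm <- read_expression_table(file.path(data_dir, "expression_fpkm.tsv"),
                              "FPKM", design)
gene_sets <- read.delim(file.path(data_dir, "gene_sets.tsv"))

expressed <- coding_ids[apply(fpkm$values[coding_ids, , drop = FALSE],
                              1, max) >= 0.5]
population <- sub("\\.t1$", "", expressed)
de_cod <- call_de(de_table(subset_features(fpkm, expressed)))
study <- sub("\\.t1$", "", de_cod$feature_id)

res <- enrich(study, population, gene_sets[c("term", "gene")])
write.table(res, file.path(out_dir, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("tested terms with >= 1 hit: %d; enriched at q < 0.05: %d\n",
            nrow(res), sum(res$qvalue < 0.05)))
print(head(res[c("term_id", "k", "K", "rich_factor", "pvalue",
                 "qvalue")], 5), row.names = FALSE)
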