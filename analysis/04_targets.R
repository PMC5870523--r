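#!/usr/bin/env Rscript
# Stage 4: lncRNA target prediction.
#
# Cis: coding genes within 10 kb / 100 kb of each lncRNA locus (both
# directions, signed edge-to-edge distance). Trans: Pearson co-expression
# across all six samples with |r| >= 0.95, p < 0.01 and BH FDR < 0.01
# over the full lncRNA x gene pair family.

suppressPackageStartupMessages(library(cernet))

data_dir <- "results/analysis/data"
out_dir <- "results/analysis"
design <- read_design(file.path(data_dir, "design.tsv"))
coding_ids <- readLines(file.path(data_dir, "coding_ids.txt"))
known_lnc <- readLines(file.path(data_dir, "known_lncrna_ids.txt"))
novel_lnc <- readLines(file.path(out_dir, "novel_lncrna_ids.txt"))
models <- read_gtf(file.path(data_dir, "annotation.gtf"),
                   coding_ids = coding_ids, known_lnc_ids = known_lnc)
fpkm <- read_expression_table(file.path(data_dir, "expression_fpkm.tsv"),
                              "FPKM", design)

lnc_ids <- union(intersect(known_lnc, names(models)), novel_lnc)
cis <- cis_targets(models[lnc_ids], models[coding_ids])
trans <- trans_targets(subset_features(fpkm, lnc_ids),
                       subset_features(fpkm, coding_ids))
write.table(cis, file.path(out_dir, "cis_targets.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(trans, file.path(out_dir, "trans_targets.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("cis pairs: %d (%d in the 10k window, %d in the 100k window)\n",
            nrow(cis), sum(cis$window_class == "10k"),
            sum(cis$window_class == "100k")))
cat(sprintf("trans pairs passing the full screen: %d\n", nrow(trans)))
man <- jsonlite::read_json(file.path(data_dir, "manifest.json"),
                           simplifyVector = TRUE)
key <- paste(man$trans_pairs$lnc_id, man$trans_pairs$gene_id)
cat(sprintf("planted trans pairs recovered: %d/%d\n",
            sum(key %in% paste(trans$lnc_id, trans$gene_id)),
            length(key)))
ck <- paste(man$cis_pairs$lnc_id, man$cis_pairs$gene_id,
            man$cis_pairs$distance)
cat(sprintf("planted cis pairs recovered at the planted distance: %d/%d\n",
            sum(ck %in% paste(cis$lnc_id, cis$gene_id, cis$distance)),
            length(ck)))
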