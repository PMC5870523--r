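#!/usr/bin/env Rscript
# Stage 2: five-criterion novel-lncRNA identification.
#
# Runs the filter cascade (>= 2 exons; spliced length > 200 bp; known
# lncRNAs set aside; max FPKM >= 0.5; unanimously noncoding by the
# coding-potential predictors) and writes the funnel report.

suppressPackageStartupMessages(library(cernet))

data_dir <- "results/analysis/data"
out_dir <- "results/analysis"
design <- read_design(file.path(data_dir, "design.tsv"))
models <- read_gtf(file.path(data_dir, "annotation.gtf"),
                   coding_ids = readLines(file.path(data_dir, "coding_ids.txt")),
                   known_lnc_ids = readLines(file.path(data_dir, "known_lncrna_ids.txt")))
fpkm <- read_expression_table(file.path(data_dir, "expression_fpkm.tsv"),
                              "FPKM", design)
seqs <- read_fasta(file.path(data_dir, "transcripts.fa"))

res <- filter_cascade(models, readLines(file.path(data_dir, "known_lncrna_ids.txt")),
                      fpkm, list(orf = make_orf_predictor(seqs)))
write.table(res$report, file.path(out_dir, "filter_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(res$novel_lnc_ids, file.path(out_dir, "novel_lncrna_ids.txt"))

cat("Filter funnel (surviving transcripts per step):\n")
print(res$report, row.names = FALSE)
cat(sprintf("novel lncRNAs: %d; known lncRNAs set aside: %d; TUCP: %d\n",
            length(res$novel_lnc_ids), length(res$known_lnc_ids),
            length(res$tucp_ids)))
man <- jsonlite::read_json(file.path(data_dir, "manifest.json"),
                           simplifyVector = TRUE)
planted <- man$features$feature_id[man$features$class == "novel_lnc"]
cat(sprintf("planted novel lncRNAs recovered: %d/%d\n",
            sum(planted %in% res$novel_lnc_ids), length(planted)))
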