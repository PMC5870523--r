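#!/usr/bin/env Rscript
# Stage 5: miRNA response elements and ceRNA triads.
#
# Scans lncRNA and mRNA sequences for canonical seed sites (8mer >
# 7mer-m8 > 7mer-A1 > 6mer), detects shared MREs, and assembles
# direction-concordant lncRNA-miRNA-mRNA triads (decoy - center -
# target), exporting the network as SIF and GraphML.

suppressPackageStartupMessages(library(cernet))

data_dir <- "results/analysis/data"
out_dir <- "results/analysis"
design <- read_design(file.path(data_dir, "design.tsv"))
coding_ids <- readLines(file.path(data_dir, "coding_ids.txt"))
known_lnc <- readLines(file.path(data_dir, "known_lncrna_ids.txt"))
novel_lnc <- readLines(file.path(out_dir, "novel_lncrna_ids.txt"))
seqs <- read_fasta(file.path(data_dir, "transcripts.fa"))
mirnas <- read_fasta(file.path(data_dir, "mirnas.fa"))
fpkm <- read_expression_table(file.path(data_dir, "expression_fpkm.tsv"),
                              "FPKM", design)
tpm <- read_expression_table(file.path(data_dir, "expression_tpm.tsv"),
                             "TPM", design)
trans <- read.delim(file.path(out_dir, "trans_targets.tsv"))
cis <- read.delim(file.path(out_dir, "cis_targets.tsv"))

lnc_ids <- union(known_lnc, novel_lnc)
sites_lnc <- scan_seed_sites(mirnas, seqs[lnc_ids])
sites_mrna <- scan_seed_sites(mirnas, seqs[coding_ids])
shared <- shared_mres(sites_lnc, sites_mrna)

de_tx <- de_table(fpkm)
de_mir <- de_table(tpm)
triads <- build_triads(
  call_de(de_tx[de_tx$feature_id %in% lnc_ids, ]), call_de(de_mir),
  call_de(de_tx[de_tx$feature_id %in% coding_ids, ]), shared, trans)

write.table(shared, file.path(out_dir, "shared_mres.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(triads, file.path(out_dir, "triads.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
tx2gene <- sub("\\.t1$", "", c(lnc_ids, coding_ids))
names(tx2gene) <- c(lnc_ids, coding_ids)
tab <- triad_table(triads, cis, transcript_gene_map = tx2gene)
write.table(tab, file.path(out_dir, "triad_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_network(triads, "SIF", file.path(out_dir, "network.sif"))
write_network(triads, "GraphML", file.path(out_dir, "network.graphml"))

cat(sprintf("seed sites: %d on lncRNAs, %d on mRNAs; shared MREs: %d\n",
            nrow(sites_lnc), nrow(sites_mrna), nrow(shared)))
cat(sprintf("ceRNA triads: %d (%d up-down-up, %d down-up-down)\n",
            nrow(triads), sum(triads$pattern == "up-down-up"),
            sum(triads$pattern == "down-up-down")))
man <- jsonlite::read_json(file.path(data_dir, "manifest.json"),
                           simplifyVector = TRUE)
key <- paste(man$triads$lnc_id, man$triads$mirna_id, man$triads$mrna_id)
got <- paste(triads$lnc_id, triads$mirna_id, triads$mrna_id)
cat(sprintf("planted triads recovered: %d/%d; non-planted triads: %d\n",
            sum(key %in% got), length(key), sum(!got %in% key)))
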