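#' Pipeline configuration
#'
#' Gathers every input path and numeric threshold of the end-to-end run.
#' `input_dir` must contain the file set written by [simulate_dataset()]
#' (or equivalently named real inputs): `annotation.gtf`,
#' `transcripts.fa`, `mirnas.fa`, `expression_fpkm.tsv`,
#' `expression_tpm.tsv`, `design.tsv`, `coding_ids.txt`,
#' `known_lncrna_ids.txt`, `gene_sets.tsv`.
#'
#' @param input_dir directory of input files.
#' @param out_dir optional output directory for result tables and network
#'   exports.
#' @param alpha DE p-value threshold (strict <, default 0.05).
#' @param r_min,p_max,fdr_max trans-screen thresholds (defaults 0.95,
#'   0.01, 0.01).
#' @param fpkm_min expression floor for filter step 4 and the enrichment
#'   population (default 0.5).
#' @param length_min,exon_min lncRNA filter structure thresholds
#'   (defaults 200 bp strict, 2 exons).
#' @param orf_threshold ORF predictor threshold in codons (default 100).
#' @param windows cis window half-widths in bp.
#' @param require_positive_lnc_mrna_r,keep_discordant triad gates (see
#'   [build_triads()]).
#' @param seed integer recorded in the run manifest (the pipeline itself
#'   is deterministic).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(input_dir, out_dir = NULL, alpha = 0.05,
                            r_min = 0.95, p_max = 0.01, fdr_max = 0.01,
                            fpkm_min = 0.5, length_min = 200,
                            exon_min = 2, orf_threshold = 100,
                            windows = c(10000, 100000),
                            require_positive_lnc_mrna_r = TRUE,
                            keep_discordant = FALSE, seed = 1L) {
  stopifnot(alpha > 0, alpha <= 1, r_min >= 0, r_min <= 1, p_max > 0,
            fdr_max > 0, fpkm_min >= 0, length_min >= 0, exon_min >= 1,
            orf_threshold >= 1, all(windows > 0))
  structure(as.list(environment()), class = "PipelineConfig")
}

# run one stage, prefixing failures with the stage name
pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full ceRNA-network pipeline
#'
#' Executes, in order: the novel-lncRNA filter cascade, differential
#' expression of mRNAs/lncRNAs/miRNAs (catagen vs anagen), cis and trans
#' lncRNA target prediction, miRNA seed-site scanning and shared-MRE
#' detection, ceRNA triad assembly with pattern classification, and
#' over-representation analysis of the DE coding genes. When
#' `config$out_dir` is set, writes all result tables (TSV), SIF and
#' GraphML network exports, and a machine-readable run manifest (JSON)
#' with the serialized configuration, its hash, and per-stage counts.
#'
#' @param config a [pipeline_config()].
#' @return list with elements `filter`, `de_mrna`, `de_lnc`, `de_mirna`
#'   (full tables), `de_mrna_called`, `de_lnc_called`, `de_mirna_called`,
#'   `cis`, `trans`, `sites_lnc`, `sites_mrna`, `shared`, `triads`,
#'   `triad_table`, `enrichment`, `counts` (named stage-count vector) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  p <- function(f) file.path(config$input_dir, f)
  needed <- c("annotation.gtf", "transcripts.fa", "mirnas.fa",
              "expression_fpkm.tsv", "expression_tpm.tsv", "design.tsv",
              "coding_ids.txt", "known_lncrna_ids.txt", "gene_sets.tsv")
  missing <- needed[!file.exists(p(needed))]
  if (length(missing))
    stop("missing input file(s) in ", config$input_dir, ": ",
         paste(missing, collapse = ", "))

  inputs <- pipeline_stage("load_inputs", {
    design <- read_design(p("design.tsv"))
    coding_ids <- readLines(p("coding_ids.txt"))
    known_lnc_ids <- readLines(p("known_lncrna_ids.txt"))
    models <- read_gtf(p("annotation.gtf"), coding_ids = coding_ids,
                       known_lnc_ids = known_lnc_ids)
    fpkm <- read_expression_table(p("expression_fpkm.tsv"), "FPKM", design)
    tpm <- read_expression_table(p("expression_tpm.tsv"), "TPM", design)
    if (nrow(fpkm$values) == 0 || nrow(tpm$values) == 0)
      stop("empty expression matrix")
    list(design = design, coding_ids = coding_ids,
         known_lnc_ids = known_lnc_ids, models = models, fpkm = fpkm,
         tpm = tpm, tx_seqs = read_fasta(p("transcripts.fa")),
         mirna_seqs = read_fasta(p("mirnas.fa")),
         gene_sets = utils::read.delim(p("gene_sets.tsv"),
                                       stringsAsFactors = FALSE))
  })

  filter <- pipeline_stage("lncrna_filter", {
    predictor <- make_orf_predictor(inputs$tx_seqs,
                                    config$orf_threshold)
    filter_cascade(inputs$models, inputs$known_lnc_ids, inputs$fpkm,
                   list(orf = predictor), exon_min = config$exon_min,
                   length_min = config$length_min,
                   fpkm_min = config$fpkm_min)
  })
  lnc_ids <- union(intersect(inputs$known_lnc_ids,
                             names(inputs$models)),
                   filter$novel_lnc_ids)
  mrna_ids <- intersect(inputs$coding_ids, names(inputs$models))

  de <- pipeline_stage("diff_expr", {
    de_all <- de_table(inputs$fpkm)
    list(mrna = de_all[de_all$feature_id %in% mrna_ids, ],
         lnc = de_all[de_all$feature_id %in% lnc_ids, ],
         mirna = de_table(inputs$tpm))
  })
  de_mrna_called <- call_de(de$mrna, config$alpha)
  de_lnc_called <- call_de(de$lnc, config$alpha)
  de_mirna_called <- call_de(de$mirna, config$alpha)

  targets <- pipeline_stage("targets", {
    lnc_models <- inputs$models[lnc_ids]
    mrna_models <- inputs$models[mrna_ids]
    list(cis = cis_targets(lnc_models, mrna_models, config$windows),
         trans = trans_targets(subset_features(inputs$fpkm, lnc_ids),
                               subset_features(inputs$fpkm, mrna_ids),
                               r_min = config$r_min,
                               p_max = config$p_max,
                               fdr_max = config$fdr_max))
  })

  mre <- pipeline_stage("mre", {
    sites_lnc <- scan_seed_sites(inputs$mirna_seqs,
                                 inputs$tx_seqs[lnc_ids])
    sites_mrna <- scan_seed_sites(inputs$mirna_seqs,
                                  inputs$tx_seqs[mrna_ids])
    list(sites_lnc = sites_lnc, sites_mrna = sites_mrna,
         shared = shared_mres(sites_lnc, sites_mrna))
  })

  triads <- pipeline_stage("cerna", {
    build_triads(
      de_lnc_called, de_mirna_called, de_mrna_called, mre$shared,
      targets$trans,
      require_positive_lnc_mrna_r = config$require_positive_lnc_mrna_r,
      keep_discordant = config$keep_discordant,
      lnc_universe = de$lnc$feature_id,
      mirna_universe = de$mirna$feature_id,
      mrna_universe = de$mrna$feature_id)
  })
  tx2gene <- stats::setNames(
    vapply(inputs$models, `[[`, "", "gene_id"), names(inputs$models))
  cis_gene_pairs <- targets$cis
  triad_tab <- triad_table(triads, cis_gene_pairs,
                           transcript_gene_map = tx2gene)

  enr <- pipeline_stage("enrichment", {
    expressed <- mrna_ids[apply(
      inputs$fpkm$values[mrna_ids, , drop = FALSE], 1, max) >=
        config$fpkm_min]
    population <- unique(unname(tx2gene[expressed]))
    study <- intersect(unique(unname(tx2gene[de_mrna_called$feature_id])),
                       population)
    enrich(study, population, inputs$gene_sets[c("term", "gene")])
  })

  counts <- c(
    transcripts = length(inputs$models),
    known_lncRNA = length(filter$known_lnc_ids),
    novel_lncRNA = length(filter$novel_lnc_ids),
    tucp = length(filter$tucp_ids),
    de_mrna = nrow(de_mrna_called),
    de_mrna_up = sum(de_mrna_called$direction == "up"),
    de_mrna_down = sum(de_mrna_called$direction == "down"),
    de_lncRNA = nrow(de_lnc_called),
    de_lncRNA_up = sum(de_lnc_called$direction == "up"),
    de_lncRNA_down = sum(de_lnc_called$direction == "down"),
    de_mirna = nrow(de_mirna_called),
    cis_pairs = nrow(targets$cis),
    trans_pairs = nrow(targets$trans),
    shared_mres = nrow(mre$shared),
    triads = nrow(triads),
    triads_up_down_up = sum(triads$pattern == "up-down-up"),
    triads_down_up_down = sum(triads$pattern == "down-up-down"),
    enriched_terms = sum(enr$qvalue < 0.05))

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(config = unclass(config),
                   config_md5 = unname(tools::md5sum(tmp)),
                   counts = as.list(counts))
  unlink(tmp)

  result <- list(filter = filter, de_mrna = de$mrna, de_lnc = de$lnc,
                 de_mirna = de$mirna, de_mrna_called = de_mrna_called,
                 de_lnc_called = de_lnc_called,
                 de_mirna_called = de_mirna_called, cis = targets$cis,
                 trans = targets$trans, sites_lnc = mre$sites_lnc,
                 sites_mrna = mre$sites_mrna, shared = mre$shared,
                 triads = triads, triad_table = triad_tab,
                 enrichment = enr, counts = counts, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(config$out_dir, f)
    wt <- function(df, f) utils::write.table(
      df, o(f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(filter$report, "filter_report.tsv")
    wt(de$mrna, "de_mrna.tsv"); wt(de$lnc, "de_lncrna.tsv")
    wt(de$mirna, "de_mirna.tsv")
    wt(targets$cis, "cis_targets.tsv")
    wt(targets$trans, "trans_targets.tsv")
    wt(rbind(mre$sites_lnc, mre$sites_mrna), "seed_sites.tsv")
    wt(mre$shared, "shared_mres.tsv")
    wt(triads, "triads.tsv"); wt(triad_tab, "triad_table.tsv")
    wt(enr, "enrichment.tsv")
    write_network(triads, "SIF", o("network.sif"))
    write_network(triads, "GraphML", o("network.graphml"))
    jsonlite::write_json(manifest, o("run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
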