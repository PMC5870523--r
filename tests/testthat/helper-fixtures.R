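# Shared synthetic fixtures, memoized per session so several test files
# can reuse the same simulated dataset without regenerating it.

.fixture_cache <- new.env(parent = emptyenv())

small_config <- function(...) {
  defaults <- list(
    seed = 42L, n_coding = 80L, n_lnc_known = 15L, n_lnc_novel = 15L,
    n_mirna = 10L, n_planted_triads = 3L, n_extra_trans_pairs = 3L,
    n_cis_10k = 3L, n_cis_100k = 3L, n_decoy_single_exon = 3L,
    n_decoy_short = 3L, n_decoy_low_expr = 3L, n_decoy_coding_like = 3L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

tiny_config <- function(...) {
  defaults <- list(
    seed = 11L, n_coding = 40L, n_lnc_known = 8L, n_lnc_novel = 8L,
    n_mirna = 6L, n_planted_triads = 2L, n_extra_trans_pairs = 2L,
    n_cis_10k = 1L, n_cis_100k = 1L, n_decoy_single_exon = 1L,
    n_decoy_short = 1L, n_decoy_low_expr = 1L, n_decoy_coding_like = 1L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

cached_sim <- function(key, cfg, out_dir = NULL) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_dataset(cfg, out_dir = out_dir)
  .fixture_cache[[key]]
}

# noise-free small dataset shared by filter / targets / mre / pipeline tests
small_sim0 <- function() cached_sim("small0", small_config(noise_sd = 0))

# hand-built transcript models for boundary tests
toy_model <- function(id, exons, gene = sub("\\..*$", "", id),
                      chrom = "chr1", strand = "+", biotype = "unknown") {
  TranscriptModel(id, gene, chrom, strand, exons, biotype)
}

toy_expr <- function(values, unit = "FPKM") {
  n <- ncol(values)
  stopifnot(n %% 2 == 0)
  samples <- c(sprintf("anagen_%d", seq_len(n / 2)),
               sprintf("catagen_%d", seq_len(n / 2)))
  colnames(values) <- samples
  ExpressionMatrix(values, unit,
                   stats::setNames(rep(c("anagen", "catagen"),
                                       each = n / 2), samples))
}
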