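test_that("pattern classification is total with exactly two concordant cases", {
  combos <- expand.grid(l = c("up", "down"), m = c("up", "down"),
                        g = c("up", "down"), stringsAsFactors = FALSE)
  patterns <- mapply(classify_pattern, combos$l, combos$m, combos$g)
  expect_length(patterns, 8)
  expect_equal(sum(patterns != "discordant"), 2)
  expect_equal(unname(patterns[combos$l == "up" & combos$m == "down" &
                                 combos$g == "up"]), "up-down-up")
  expect_equal(unname(patterns[combos$l == "down" & combos$m == "up" &
                                 combos$g == "down"]), "down-up-down")
  expect_error(classify_pattern("up", "none", "down"), "'up' or 'down'")
})

make_triad_inputs <- function() {
  de <- function(ids, dirs) data.frame(
    feature_id = ids, log2fc = ifelse(dirs == "up", 2, -2),
    pvalue = 0.001, direction = dirs, stringsAsFactors = FALSE)
  shared <- data.frame(
    mirna_id = c("M1", "M2"), lnc_id = c("L1", "L2"),
    mrna_id = c("G1", "G2"), n_lnc_sites = 1L, n_mrna_sites = 1L,
    lnc_site_types = "8mer", mrna_site_types = "8mer",
    stringsAsFactors = FALSE)
  corr <- data.frame(lnc_id = c("L1", "L2"), gene_id = c("G1", "G2"),
                     r = c(0.99, 0.97), n = 6, pvalue = 1e-4,
                     qvalue = 1e-4, stringsAsFactors = FALSE)
  list(de = de, shared = shared, corr = corr)
}

test_that("triads require DE, shared MRE and positive correlation", {
  inp <- make_triad_inputs()
  t1 <- build_triads(inp$de("L1", "up"), inp$de("M1", "down"),
                     inp$de("G1", "up"), inp$shared, inp$corr)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$pattern, "up-down-up")
  expect_equal(t1$lnc_mrna_r, 0.99)

  # all-up trio is discordant: suppressed by default, kept on request
  t2 <- build_triads(inp$de("L1", "up"), inp$de("M1", "up"),
                     inp$de("G1", "up"), inp$shared, inp$corr)
  expect_equal(nrow(t2), 0)
  t2k <- build_triads(inp$de("L1", "up"), inp$de("M1", "up"),
                      inp$de("G1", "up"), inp$shared, inp$corr,
                      keep_discordant = TRUE)
  expect_equal(t2k$pattern, "discordant")

  # a negatively correlated pair fails the positivity gate only when set
  neg <- inp$corr; neg$r[1] <- -0.99
  t3 <- build_triads(inp$de("L1", "down"), inp$de("M1", "up"),
                     inp$de("G1", "down"), inp$shared, neg)
  expect_equal(nrow(t3), 0)
  t3n <- build_triads(inp$de("L1", "down"), inp$de("M1", "up"),
                      inp$de("G1", "down"), inp$shared, neg,
                      require_positive_lnc_mrna_r = FALSE)
  expect_equal(nrow(t3n), 1)

  # a pair absent from the correlation screen never forms a triad
  t4 <- build_triads(inp$de("L1", "up"), inp$de("M1", "down"),
                     inp$de("G1", "up"), inp$shared, inp$corr[0, ])
  expect_equal(nrow(t4), 0)

  # molecules outside the tested universe are an error
  expect_error(
    build_triads(inp$de("L1", "up"), inp$de("M1", "down"),
                 inp$de("G1", "up"), inp$shared, inp$corr,
                 mirna_universe = "M1"),
    "M2")
})

test_that("removing a DE molecule removes exactly its triads", {
  inp <- make_triad_inputs()
  de_l <- inp$de(c("L1", "L2"), c("up", "down"))
  de_m <- inp$de(c("M1", "M2"), c("down", "up"))
  de_g <- inp$de(c("G1", "G2"), c("up", "down"))
  both <- build_triads(de_l, de_m, de_g, inp$shared, inp$corr)
  expect_equal(nrow(both), 2)
  dropped <- build_triads(de_l[de_l$feature_id != "L1", ], de_m, de_g,
                          inp$shared, inp$corr)
  expect_equal(dropped$lnc_id, "L2")
  expect_equal(nrow(dropped), nrow(both) - sum(both$lnc_id == "L1"))
})

test_that("the gene-centric report groups and sorts triad partners", {
  triads <- data.frame(
    lnc_id = c("L2", "L1"), mirna_id = c("M2", "M1"),
    mrna_id = c("G1.t1", "G1.t1"), pattern = "up-down-up",
    lnc_mrna_r = 0.99, n_lnc_sites = 1L, n_mrna_sites = 1L,
    lnc_site_types = "8mer", mrna_site_types = "8mer",
    stringsAsFactors = FALSE)
  tab <- triad_table(triads,
                     transcript_gene_map = c(G1.t1 = "G1"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$gene, "G1")
  expect_equal(tab$lnc_in_cis, "")        # no cis annotation supplied
  expect_equal(tab$lnc_in_trans, "L1,L2") # deduplicated, sorted
  expect_equal(tab$mirnas, "M1,M2")

  cis <- data.frame(lnc_id = "L1", gene_id = "G1", distance = -5000,
                    window = 10000, window_class = "10k",
                    stringsAsFactors = FALSE)
  tab2 <- triad_table(triads, cis, transcript_gene_map = c(G1.t1 = "G1"))
  expect_equal(tab2$lnc_in_cis, "L1")
  expect_equal(tab2$lnc_in_trans, "L2")

  expect_error(triad_table(triads, transcript_gene_map = c(other = "x")),
               "without gene mapping")
})

test_that("pipeline triads on the fixture pass an independent validator", {
  sim <- small_sim0()
  dir <- withr::local_tempdir()
  simulate_dataset(small_config(noise_sd = 0), out_dir = dir)
  res <- run_pipeline(pipeline_config(dir))
  expect_gt(nrow(res$triads), 0)
  # re-check all three gates independently for every emitted triad
  de_ids <- list(lnc = res$de_lnc_called$feature_id,
                 mir = res$de_mirna_called$feature_id,
                 mrna = res$de_mrna_called$feature_id)
  corr_key <- paste(res$trans$lnc_id, res$trans$gene_id)
  shared_key <- paste(res$shared$mirna_id, res$shared$lnc_id,
                      res$shared$mrna_id)
  for (i in seq_len(nrow(res$triads))) {
    tr <- res$triads[i, ]
    expect_true(tr$lnc_id %in% de_ids$lnc)
    expect_true(tr$mirna_id %in% de_ids$mir)
    expect_true(tr$mrna_id %in% de_ids$mrna)
    expect_true(paste(tr$mirna_id, tr$lnc_id, tr$mrna_id) %in% shared_key)
    expect_true(paste(tr$lnc_id, tr$mrna_id) %in% corr_key)
    expect_gt(tr$lnc_mrna_r, 0)
    expect_true(tr$pattern %in% c("up-down-up", "down-up-down"))
  }
})
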