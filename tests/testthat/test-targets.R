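test_that("pearson_r matches the product-moment formula", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)

  y <- c(2, 1, 4, 3, 6, 5)
  # from-scratch sum formula
  n <- length(x)
  r_formula <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(pearson_r(x, y), r_formula)
  expect_equal(pearson_r(y, x), pearson_r(x, y))       # symmetry
  expect_equal(pearson_r(3 * x + 2, y), pearson_r(x, y))  # affine
  expect_true(is.na(pearson_r(rep(1, 6), y)))          # zero variance
  expect_error(pearson_r(x, y[-1]), "equal length")
  expect_error(pearson_r(1:2, 2:3), "3 observations")
})

test_that("correlation p-values follow the exact t distribution", {
  expect_equal(correlation_pvalue(0, 10), 1)
  expect_lt(correlation_pvalue(0.9999, 6), 1e-6)
  expect_equal(correlation_pvalue(1, 6), 0)

  # independent oracle: stats::cor.test on data realizing a given r
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    ct <- stats::cor.test(x, y)
    expect_equal(correlation_pvalue(unname(ct$estimate), 8), ct$p.value,
                 tolerance = 1e-12)
  }
  # the screen's operating point: r = 0.95 with n = 6
  ct <- stats::cor.test(c(1, 2, 3, 4, 5, 6),
                        c(1.1, 1.9, 3.4, 3.6, 5.6, 5.4))
  expect_equal(correlation_pvalue(unname(ct$estimate), 6), ct$p.value)
})

test_that("cis windows honour their boundaries exactly", {
  lnc <- list(toy_model("L1.t1", rbind(c(50000, 51000))))
  genes <- list(
    toy_model("near.t1", rbind(c(39000, 40001)), gene = "near",
              biotype = "coding"),     # ends 9,999 bp before the lncRNA
    toy_model("far.t1", rbind(c(61001, 62000)), gene = "far",
              biotype = "coding"),     # starts 10,001 bp after it
    toy_model("inside.t1", rbind(c(50500, 50800)), gene = "inside",
              biotype = "coding"))
  pairs <- cis_targets(lnc, genes)
  near <- pairs[pairs$gene_id == "near", ]
  expect_equal(near$distance, -9999)
  expect_equal(near$window_class, "10k")
  far <- pairs[pairs$gene_id == "far", ]
  expect_equal(far$distance, 10001)
  expect_equal(far$window_class, "100k")   # excluded from 10k
  expect_equal(pairs$distance[pairs$gene_id == "inside"], 0)
})

test_that("cis search equals the quadratic brute-force oracle", {
  sim <- small_sim0()
  tt <- transcript_table(sim$transcripts)
  lnc_ids <- tt$transcript_id[grepl("^(KLNC|XLOC)", tt$transcript_id)]
  lnc_models <- sim$transcripts[lnc_ids]
  gene_models <- sim$transcripts[sim$coding_ids]
  got <- cis_targets(lnc_models, gene_models)
  want <- oracle_cis_pairs(transcript_table(lnc_models),
                           transcript_table(gene_models),
                           c(10000, 100000))
  expect_equal(got[c("lnc_id", "gene_id", "distance", "window")], want,
               ignore_attr = TRUE)
  # and the oracle recovers every planted pair with its planted distance
  man <- sim$manifest$cis_pairs
  key <- paste(man$lnc_id, man$gene_id, man$distance)
  expect_true(all(key %in% paste(got$lnc_id, got$gene_id, got$distance)))
})

test_that("the trans screen keeps planted pairs and is threshold-monotone", {
  sim <- small_sim0()
  lnc_ids <- grep("^(KLNC|XLOC)", feature_ids(sim$fpkm), value = TRUE)
  lnc <- subset_features(sim$fpkm, lnc_ids)
  cod <- subset_features(sim$fpkm, sim$coding_ids)
  kept <- trans_targets(lnc, cod)
  man <- sim$manifest$trans_pairs
  key <- paste(man$lnc_id, man$gene_id)
  got <- paste(kept$lnc_id, kept$gene_id)
  expect_true(all(key %in% got))
  # planted partners are exactly proportional without noise: r = 1
  expect_equal(kept$r[match(key, got)], rep(1, length(key)))

  # relaxing any threshold never shrinks the retained set
  tighter <- trans_targets(lnc, cod, r_min = 0.99, p_max = 0.001,
                           fdr_max = 0.001)
  expect_true(all(paste(tighter$lnc_id, tighter$gene_id) %in% got))
  expect_error(
    trans_targets(subset_features(lnc, lnc_ids[1:2]), cod), NA)

  few <- sim$fpkm
  few$values <- few$values[, 1:2]
  few$design <- few$design[1:2]
  expect_error(trans_targets(few, few), "3 shared samples")
})
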