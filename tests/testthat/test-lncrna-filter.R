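make_toy_cascade <- function() {
  # hand-built transcripts exercising each criterion boundary
  models <- list(
    toy_model("single.t1", rbind(c(1000, 1299))),              # 1 exon
    toy_model("short.t1", rbind(c(2000, 2099), c(2200, 2299))),# exactly 200
    toy_model("known.t1", rbind(c(3000, 3199), c(3300, 3500))),
    toy_model("low.t1", rbind(c(4000, 4199), c(4300, 4500))),  # low FPKM
    toy_model("coding.t1", rbind(c(5000, 5299), c(5400, 5702))),
    toy_model("novel.t1", rbind(c(6000, 6199), c(6300, 6500))))
  vals <- matrix(5, 6, 6, dimnames = list(
    vapply(models, `[[`, "", "transcript_id"), NULL))
  vals["low.t1", ] <- 0.4  # max FPKM below the 0.5 floor
  expr <- toy_expr(vals)
  seqs <- c(
    single.t1 = random_dna(300), short.t1 = random_dna(200),
    known.t1 = random_dna(402), low.t1 = random_dna(402),
    coding.t1 = paste0(random_dna(100), "ATG",
                       strrep("GCT", 150), "TAA", random_dna(100)),
    novel.t1 = paste0(strrep("CT", 200), "AA"))
  list(models = models, expr = expr,
       predictors = list(orf = make_orf_predictor(seqs)), seqs = seqs)
}

test_that("each criterion removes its designed failures", {
  set.seed(3)
  toy <- make_toy_cascade()
  res <- filter_cascade(toy$models, known_lnc_ids = "known.t1",
                        toy$expr, toy$predictors)
  s <- res$surviving
  expect_false("single.t1" %in% s$step1_exons)       # < 2 exons
  expect_true("short.t1" %in% s$step1_exons)
  expect_false("short.t1" %in% s$step2_length)       # exactly 200, strict
  expect_equal(res$known_lnc_ids, "known.t1")        # set aside at step 3
  expect_false("known.t1" %in% s$step3_unknown)
  expect_false("low.t1" %in% s$step4_expression)     # max FPKM 0.4 < 0.5
  expect_false("coding.t1" %in% res$novel_lnc_ids)   # 151-codon ORF
  expect_equal(res$novel_lnc_ids, "novel.t1")
  expect_true(all(diff(res$report$n_surviving) <= 0))
})

test_that("the cascade is order-independent and idempotent", {
  set.seed(4)
  sim <- small_sim0()
  predictors <- list(orf = make_orf_predictor(sim$transcript_seqs))
  res <- filter_cascade(sim$transcripts, sim$known_lnc_ids, sim$fpkm,
                        predictors)
  perm <- sample(seq_along(sim$transcripts))
  res_perm <- filter_cascade(sim$transcripts[perm], sim$known_lnc_ids,
                             sim$fpkm, predictors)
  for (step in names(res$surviving))
    expect_setequal(res$surviving[[step]], res_perm$surviving[[step]])

  # feeding the surviving set back through returns it unchanged
  again <- filter_cascade(sim$transcripts[res$novel_lnc_ids],
                          sim$known_lnc_ids,
                          subset_features(sim$fpkm, res$novel_lnc_ids),
                          predictors)
  expect_setequal(again$novel_lnc_ids, res$novel_lnc_ids)
  expect_true(all(again$report$n_surviving ==
                    length(res$novel_lnc_ids)))
})

test_that("cascade results match independent set operations on the fixture", {
  sim <- small_sim0()
  res <- filter_cascade(sim$transcripts, sim$known_lnc_ids, sim$fpkm,
                        list(orf = make_orf_predictor(sim$transcript_seqs)))
  tt <- transcript_table(sim$transcripts)
  s1 <- tt$transcript_id[tt$n_exons >= 2]
  s2 <- intersect(s1, tt$transcript_id[tt$length > 200])
  s3 <- setdiff(s2, sim$known_lnc_ids)
  mx <- apply(sim$fpkm$values[s3, , drop = FALSE], 1, max)
  s4 <- s3[mx >= 0.5]
  s5 <- s4[vapply(sim$transcript_seqs[s4],
                  function(s) oracle_orf_score(s) < 100, TRUE)]
  expect_equal(res$report$n_surviving,
               lengths(list(tt$transcript_id, s1, s2, s3, s4, s5)))
  expect_setequal(res$novel_lnc_ids, s5)
  # the planted novel lncRNAs all survive on the noise-free fixture
  man <- sim$manifest$features
  expect_setequal(res$novel_lnc_ids,
                  man$feature_id[man$class == "novel_lnc"])
})

test_that("ORF scoring matches a brute-force 3-frame scan", {
  # constructed: ATG + 99 codons + TAA -> exactly 100 codons -> coding
  orf100 <- paste0(random_dna(50), "ATG", strrep("GCA", 99), "TAA",
                   random_dna(30))
  expect_equal(orf_coding_potential(orf100)$score, 100)
  expect_equal(orf_coding_potential(orf100)$call, "coding")
  expect_equal(orf_coding_potential(strrep("CT", 300))$score, 0)
  expect_equal(orf_coding_potential(strrep("CT", 300))$call, "noncoding")

  set.seed(8)
  for (i in 1:50) {
    s <- random_dna(1000)
    expect_equal(orf_coding_potential(s)$score, oracle_orf_score(s),
                 label = paste("random sequence", i))
  }
})

test_that("predictor intersection follows set algebra", {
  one <- list(a = c(x = "noncoding", y = "coding", z = "noncoding"))
  expect_setequal(intersect_noncoding(one), c("x", "z"))
  two <- c(one, list(b = c(x = "coding", y = "noncoding", z = "coding")))
  expect_equal(intersect_noncoding(two), character(0))

  set.seed(9)
  ids <- paste0("t", 1:30)
  maps <- lapply(1:3, function(i)
    stats::setNames(sample(c("coding", "noncoding"), 30, TRUE), ids))
  folded <- Reduce(intersect,
                   lapply(maps, function(m) names(m)[m == "noncoding"]))
  expect_setequal(intersect_noncoding(maps), folded)
})

test_that("split predictor verdicts are reported as uncertain coding potential", {
  set.seed(10)
  toy <- make_toy_cascade()
  # second predictor disagrees on novel.t1 only
  flip <- function(ids) {
    calls <- toy$predictors$orf(ids)
    calls["novel.t1" == names(calls)] <- "coding"
    calls
  }
  res <- filter_cascade(toy$models, "known.t1", toy$expr,
                        list(orf = toy$predictors$orf, flip = flip))
  expect_false("novel.t1" %in% res$novel_lnc_ids)
  expect_true("novel.t1" %in% res$tucp_ids)
  expect_false("coding.t1" %in% res$tucp_ids)  # coding by all predictors
})

test_that("missing expression rows are reported by id", {
  toy <- make_toy_cascade()
  expr_missing <- subset_features(
    toy$expr, setdiff(rownames(toy$expr$values), "novel.t1"))
  expect_error(
    filter_cascade(toy$models, "known.t1", expr_missing, toy$predictors),
    "novel.t1")
})
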