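test_that("the same seed reproduces byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(tiny_config(seed = 99L), out_dir = d1)
  simulate_dataset(tiny_config(seed = 99L), out_dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 10)
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
})

test_that("planted seed sites follow the canonical site definitions", {
  set.seed(1)
  let7 <- "UGAGGUAGUAGGUUGUAUAGUU"
  base <- random_dna(300)
  p8 <- plant_seed_site(base, let7, "8mer")
  expect_equal(substr(p8$seq, p8$start, p8$start + 7), "CTACCTCA")
  p6 <- plant_seed_site(base, let7, "6mer")
  expect_equal(substr(p6$seq, p6$start, p6$start + 5), "TACCTC")
  expect_error(plant_seed_site("ACGT", let7, "8mer"), "too short")
})

test_that("random plants are recovered at the recorded position and type", {
  set.seed(20)
  types <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  for (i in 1:100) {
    mir <- random_dna(22)
    ty <- sample(types, 1)
    planted <- plant_seed_site(random_dna(250), mir, ty)
    hits <- oracle_seed_sites(mir, planted$seq)
    j <- which(hits$start == planted$start)
    expect_length(j, 1)
    expect_equal(hits$site_type[j], ty,
                 label = sprintf("plant %d (%s)", i, ty))
  }
})

test_that("a flat, noise-free configuration yields no DE calls", {
  sim <- simulate_dataset(tiny_config(
    seed = 5L, de_fraction = 0, noise_sd = 0, n_planted_triads = 0L,
    n_extra_trans_pairs = 0L))
  de <- call_de(de_table(sim$fpkm), alpha = 0.05)
  expect_equal(nrow(de), 0)
  de_mir <- call_de(de_table(sim$tpm), alpha = 0.05)
  expect_equal(nrow(de_mir), 0)
})

test_that("the manifest is the single source of truth for planted entities", {
  sim <- small_sim0()
  man <- sim$manifest
  # every planted entity exists in the emitted objects
  expect_true(all(man$features$feature_id %in% names(sim$transcripts)))
  expect_true(all(man$features$feature_id %in% names(sim$transcript_seqs)))
  expect_true(all(man$triads$lnc_id %in% names(sim$transcript_seqs)))
  expect_true(all(man$triads$mirna_id %in% names(sim$mirna_seqs)))
  # sequences carry the planted sites where recorded
  for (i in seq_len(nrow(man$planted_sites))) {
    ps <- man$planted_sites[i, ]
    motif <- seed_motifs(sim$mirna_seqs[[ps$mirna_id]])[[ps$site_type]]
    expect_equal(substr(sim$transcript_seqs[[ps$target_id]], ps$start,
                        ps$start + nchar(motif) - 1), motif)
  }
  # sequence lengths equal spliced transcript lengths
  expect_equal(unname(nchar(sim$transcript_seqs[man$features$feature_id])),
               man$features$length)
})

test_that("non-planted sequences carry no seed site for any catalog miRNA", {
  sim <- small_sim0()
  planted <- unique(sim$manifest$planted_sites$target_id)
  clean_ids <- setdiff(names(sim$transcript_seqs), planted)
  hits <- scan_seed_sites(sim$mirna_seqs, sim$transcript_seqs[clean_ids])
  expect_equal(nrow(hits), 0)
})

test_that("downstream recovery is perfect without noise and degrades with it", {
  noise_grid <- c(0, 1, 3)
  recall <- sapply(noise_grid, function(ns) {
    mean(sapply(1:3, function(s) {
      sim <- simulate_dataset(tiny_config(seed = 100L + s, noise_sd = ns))
      de <- call_de(de_table(sim$fpkm), 0.05)
      truth <- sim$manifest$features$feature_id[sim$manifest$features$de]
      mean(truth %in% de$feature_id)
    }))
  })
  expect_equal(recall[1], 1)
  expect_true(all(diff(recall) <= 0))
})

test_that("null data stay below 1% false-positive trans pairs", {
  sim <- simulate_dataset(tiny_config(
    seed = 77L, de_fraction = 0, n_planted_triads = 0L,
    n_extra_trans_pairs = 0L, noise_sd = 0.5))
  lnc <- subset_features(sim$fpkm, grep("LNC|XLOC",
                                        feature_ids(sim$fpkm),
                                        value = TRUE))
  cod <- subset_features(sim$fpkm, grep("^GENE", feature_ids(sim$fpkm),
                                        value = TRUE))
  res <- trans_targets(lnc, cod, keep_all = TRUE)
  expect_lte(mean(res$retained), 0.01)
})

test_that("impossible planting demands are rejected", {
  expect_error(simulation_config(n_planted_triads = 50L, n_mirna = 10L),
               "exceeds")
  expect_error(simulation_config(de_fraction = 1.2), "de_fraction")
})
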