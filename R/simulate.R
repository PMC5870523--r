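#' Simulation configuration
#'
#' Parameters of the self-contained synthetic dataset emulating a
#' 3-vs-3 anagen/catagen skin design with planted ground truth. Defaults
#' are the study conditions used throughout the package's validation:
#' ~500 transcript features plus a 30-miRNA catalog, log-normal biological
#' noise, planted differential expression at log2 effect ~N(3, 0.5),
#' planted high-correlation lncRNA-mRNA pairs, planted cis neighbours in
#' the 10 kb and 100 kb windows, and planted shared-8mer ceRNA triads.
#'
#' @param seed integer RNG seed; a fixed seed yields byte-identical
#'   outputs.
#' @param n_coding,n_lnc_known,n_lnc_novel,n_mirna feature counts.
#' @param n_samples_per_group replicates per group (default 3).
#' @param de_fraction fraction of each feature class planted as DE.
#' @param lfc_mean,lfc_sd log2 fold-change magnitude distribution
#'   (magnitudes are `|N(lfc_mean, lfc_sd)|`, signs planted).
#' @param noise_sd log2-scale sd of the multiplicative log-normal noise.
#' @param latent_sd log2-scale sd of the per-sample latent factor shared
#'   by planted trans partners.
#' @param trans_resid_frac fraction of `noise_sd` kept as pair-independent
#'   residual noise for planted trans partners (the rest of their noise is
#'   shared, modelling tight co-regulation); their expected Pearson r under
#'   noise is recorded in the manifest as `target_r`.
#' @param n_planted_triads planted ceRNA triads (8mer sites on lncRNA and
#'   mRNA for the same miRNA, concordant directions).
#' @param n_extra_trans_pairs additional planted trans pairs outside
#'   triads.
#' @param n_cis_10k,n_cis_100k planted cis neighbour pairs per window
#'   class.
#' @param cis_window_bp the two window half-widths in bp.
#' @param n_decoy_single_exon,n_decoy_short,n_decoy_low_expr,n_decoy_coding_like
#'   filter-funnel decoy transcripts failing, respectively, the exon,
#'   length, expression and coding-potential criteria.
#' @param seq_len_lnc,seq_len_coding spliced transcript lengths (bp).
#' @param mirna_len miRNA length (nt).
#' @param orf_codons ORF length planted in coding transcripts (codons).
#' @param chrom,intergenic_gap chromosome name and minimum gap between
#'   unrelated loci (bp; must exceed the largest cis window).
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1L, n_coding = 350L,
                              n_lnc_known = 60L, n_lnc_novel = 60L,
                              n_mirna = 30L, n_samples_per_group = 3L,
                              de_fraction = 0.2, lfc_mean = 3,
                              lfc_sd = 0.5, noise_sd = 0.5,
                              latent_sd = 0.4, trans_resid_frac = 0.05,
                              n_planted_triads = 5L,
                              n_extra_trans_pairs = 5L, n_cis_10k = 5L,
                              n_cis_100k = 5L,
                              cis_window_bp = c(10000L, 100000L),
                              n_decoy_single_exon = 6L,
                              n_decoy_short = 6L, n_decoy_low_expr = 6L,
                              n_decoy_coding_like = 6L,
                              seq_len_lnc = 400L, seq_len_coding = 600L,
                              mirna_len = 22L, orf_codons = 120L,
                              chrom = "chrSim1",
                              intergenic_gap = 250000L) {
  cfg <- as.list(environment())
  counts <- cfg[grep("^n_", names(cfg))]
  if (any(unlist(counts) < 0)) stop("all counts must be >= 0")
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must lie in [0, 1]")
  if (intergenic_gap <= max(cis_window_bp))
    stop("intergenic_gap must exceed the largest cis window")
  if (n_planted_triads > min(n_lnc_novel, n_mirna, n_coding))
    stop("n_planted_triads exceeds available lncRNAs, miRNAs or genes")
  if (n_extra_trans_pairs + n_planted_triads >
      min(n_lnc_known + n_lnc_novel, n_coding))
    stop("more planted trans pairs than available features")
  if (n_cis_10k + n_cis_100k > min(n_lnc_known + n_lnc_novel, n_coding))
    stop("more planted cis pairs than available features")
  structure(cfg, class = "SimulationConfig")
}

# sample() without the length-1 surprise
resample <- function(x, size = 1, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# sample a random sequence of length L containing none of `forbidden`
# (fixed motifs) and, optionally, no ORF reaching `max_orf` codons
clean_random_seq <- function(L, forbidden, max_orf = NULL,
                             max_tries = 5000L) {
  for (i in seq_len(max_tries)) {
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    if (any(vapply(forbidden, grepl, TRUE, x = s, fixed = TRUE))) next
    if (!is.null(max_orf) &&
        orf_coding_potential(s)$score >= max_orf) next
    return(s)
  }
  stop("failed to sample a clean sequence of length ", L,
       " after ", max_tries, " tries")
}

# coding sequence: UTR5 + ATG + (orf_codons - 1) non-stop codons + TAA +
# UTR3, clean of forbidden motifs; returns seq and the ORF span
clean_coding_seq <- function(L, forbidden, orf_codons,
                             max_tries = 5000L) {
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases), 1, paste,
                      collapse = "")
  sense_codons <- setdiff(all_codons, stops)
  orf_nt <- 3L * orf_codons + 3L
  if (L < orf_nt + 160L)
    stop("transcript length too short for the planted ORF")
  for (i in seq_len(max_tries)) {
    utr5 <- sample(60:120, 1)
    orf <- paste0("ATG",
                  paste(sample(sense_codons, orf_codons - 1L,
                               replace = TRUE), collapse = ""), "TAA")
    s <- paste0(
      paste(sample(bases, utr5, replace = TRUE), collapse = ""), orf,
      paste(sample(bases, L - utr5 - orf_nt, replace = TRUE),
            collapse = ""))
    if (any(vapply(forbidden, grepl, TRUE, x = s, fixed = TRUE))) next
    return(list(seq = s, orf_start = utr5 + 1L,
                orf_end = utr5 + orf_nt))
  }
  stop("failed to sample a clean coding sequence after ", max_tries,
       " tries")
}

#' Plant a canonical miRNA seed site into a sequence
#'
#' Overwrites a randomly chosen window of `seq` with the site motif of the
#' requested type for `mirna_seq`, then verifies that the insertion
#' created no additional >= 6mer match for that miRNA: outside the planted
#' footprint, only match positions already present in the input sequence
#' are tolerated (junction-created matches and in-place type upgrades are
#' re-rolled; subsites inside the footprint are inherent to the site
#' definition).
#'
#' @param seq target sequence (DNA alphabet).
#' @param mirna_seq miRNA sequence (>= 8 nt).
#' @param site_type `"8mer"`, `"7mer-m8"`, `"7mer-A1"` or `"6mer"`.
#' @param region optional `c(from, to)` window (1-based inclusive) within
#'   which the planted site must fully lie.
#' @param max_tries bounded retries before erroring.
#' @return list with `seq` (modified sequence), `start` (planted position)
#'   and `site_type`.
#' @export
plant_seed_site <- function(seq, mirna_seq,
                            site_type = c("8mer", "7mer-m8", "7mer-A1",
                                          "6mer"),
                            region = NULL, max_tries = 50L) {
  site_type <- match.arg(site_type)
  motif <- seed_motifs(mirna_seq)[[site_type]]
  k <- nchar(motif)
  lo <- if (is.null(region)) 1L else as.integer(region[1])
  hi <- (if (is.null(region)) nchar(seq) else as.integer(region[2])) - k + 1L
  if (hi < lo) stop("sequence (or region) too short for a ", site_type,
                    " site")
  base_starts <- seed_sites(mirna_seq, seq)$start
  for (i in seq_len(max_tries)) {
    pos <- resample(lo:hi)
    cand <- paste0(substr(seq, 1, pos - 1L), motif,
                   substr(seq, pos + k, nchar(seq)))
    hits <- seed_sites(mirna_seq, cand)
    inside <- hits$start >= pos & hits$start + nchar(
      seed_motifs(mirna_seq)[hits$site_type]) - 1L <= pos + k - 1L
    if (all(inside | hits$start %in% base_starts) &&
        any(hits$start == pos & hits$site_type == site_type))
      return(list(seq = cand, start = pos, site_type = site_type))
  }
  stop("could not plant a ", site_type,
       " site without stray seed matches after ", max_tries, " tries")
}

# miRNA catalog with pairwise-distinct 6-nt seed cores (m2-m7)
sample_mirna_catalog <- function(n, len, max_tries = 10000L) {
  if (n == 0) return(stats::setNames(character(0), character(0)))
  seqs <- character(0)
  cores <- character(0)
  for (i in seq_len(max_tries)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    core <- substr(s, 2, 7)
    if (core %in% cores) next
    seqs <- c(seqs, s)
    cores <- c(cores, core)
    if (length(seqs) == n) {
      names(seqs) <- sprintf("mir-%03d", seq_len(n))
      return(seqs)
    }
  }
  stop("failed to sample ", n, " miRNAs with distinct seeds")
}

# split a spliced length into n_exons exon lengths (each >= min_exon)
split_exons <- function(length, n_exons, min_exon = 50L) {
  if (n_exons == 1L) return(length)
  spare <- length - n_exons * min_exon
  if (spare < 0) stop("length too short for ", n_exons, " exons")
  cuts <- sort(resample(0:spare, n_exons - 1L, replace = TRUE))
  min_exon + diff(c(0L, cuts, spare))
}

# genomic exon matrix starting at `at`, introns of 100 bp
place_exons <- function(at, exon_lengths, intron = 100L) {
  starts <- at + cumsum(c(0L, exon_lengths[-length(exon_lengths)] +
                            intron))
  cbind(start = starts, end = starts + exon_lengths - 1L)
}

#' Generate the synthetic two-condition dataset with planted ground truth
#'
#' Builds, deterministically from `config$seed`, a complete toy dataset:
#' transcript annotation on a single synthetic chromosome (unrelated loci
#' separated by more than the largest cis window, planted cis neighbours
#' at known signed distances), transcript and miRNA sequences (non-planted
#' sequences are rejection-sampled to carry no >= 6mer seed match for any
#' catalog miRNA, so all seed sites in the dataset are planted), FPKM and
#' TPM expression tables drawn as log-normal noise around group means
#' (log2 means shifted by the planted fold changes for DE features;
#' planted trans partners share a per-sample latent factor and an equal
#' fold change, making their noise-free Pearson correlation exactly 1),
#' and a ground-truth manifest that downstream recovery tests treat as the
#' single oracle.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, all files (GTF, FASTAs,
#'   expression TSVs, design, id lists, gene sets, `manifest.json`) are
#'   written there.
#' @return list with elements `transcripts` (list of `TranscriptModel`),
#'   `transcript_seqs`, `mirna_seqs`, `fpkm`, `tpm` ([ExpressionMatrix()]),
#'   `design`, `coding_ids`, `known_lnc_ids`, `gene_sets`, `manifest` and,
#'   when written, `paths`.
#' @export
simulate_dataset <- function(config = simulation_config(),
                             out_dir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)

  mirna_seqs <- sample_mirna_catalog(config$n_mirna, config$mirna_len)
  forbidden <- vapply(mirna_seqs, function(m) seed_motifs(m)[["6mer"]], "")

  ## ---- feature inventory -------------------------------------------------
  ids <- list(
    coding = sprintf("GENE%04d.t1", seq_len(config$n_coding)),
    known_lnc = sprintf("KLNC%04d.t1", seq_len(config$n_lnc_known)),
    novel_lnc = sprintf("XLOC%04d.t1", seq_len(config$n_lnc_novel)),
    decoy_single_exon = sprintf("DSE%03d.t1",
                                seq_len(config$n_decoy_single_exon)),
    decoy_short = sprintf("DSH%03d.t1", seq_len(config$n_decoy_short)),
    decoy_low_expr = sprintf("DLE%03d.t1",
                             seq_len(config$n_decoy_low_expr)),
    decoy_coding_like = sprintf("DCL%03d.t1",
                                seq_len(config$n_decoy_coding_like)))
  tx_ids <- unlist(ids, use.names = FALSE)
  tx_class <- rep(names(ids), lengths(ids))
  gene_of <- sub("\\.t1$", "", tx_ids)
  names(tx_class) <- names(gene_of) <- tx_ids
  lnc_ids <- c(ids$known_lnc, ids$novel_lnc)

  ## ---- planted structures ------------------------------------------------
  pick <- function(pool, n, used) resample(setdiff(pool, used), n)
  used_lnc <- used_gene <- used_mir <- character(0)

  triads <- NULL
  if (config$n_planted_triads > 0) {
    t_lnc <- pick(ids$novel_lnc, config$n_planted_triads, used_lnc)
    t_gene <- pick(ids$coding, config$n_planted_triads, used_gene)
    t_mir <- pick(names(mirna_seqs), config$n_planted_triads, used_mir)
    pattern <- sample(c("up-down-up", "down-up-down"),
                      config$n_planted_triads, replace = TRUE)
    triads <- data.frame(lnc_id = t_lnc, mirna_id = t_mir,
                         mrna_id = t_gene, pattern = pattern,
                         stringsAsFactors = FALSE)
    used_lnc <- c(used_lnc, t_lnc)
    used_gene <- c(used_gene, t_gene)
    used_mir <- c(used_mir, t_mir)
  }
  extra_trans <- NULL
  if (config$n_extra_trans_pairs > 0) {
    e_lnc <- pick(lnc_ids, config$n_extra_trans_pairs, used_lnc)
    e_gene <- pick(ids$coding, config$n_extra_trans_pairs, used_gene)
    extra_trans <- data.frame(lnc_id = e_lnc, gene_id = e_gene,
                              stringsAsFactors = FALSE)
    used_lnc <- c(used_lnc, e_lnc)
    used_gene <- c(used_gene, e_gene)
  }
  trans_pairs <- rbind(
    if (!is.null(triads))
      data.frame(lnc_id = triads$lnc_id, gene_id = triads$mrna_id,
                 source = "triad", stringsAsFactors = FALSE),
    if (!is.null(extra_trans))
      data.frame(extra_trans, source = "extra", stringsAsFactors = FALSE))

  n_cis <- config$n_cis_10k + config$n_cis_100k
  cis_pairs <- NULL
  if (n_cis > 0) {
    c_lnc <- sample(lnc_ids, n_cis)
    c_gene <- pick(ids$coding, n_cis, used_gene)
    w <- sort(config$cis_window_bp)
    dist_mag <- c(if (config$n_cis_10k)
                    sample(2000:(w[1] - 1000), config$n_cis_10k),
                  if (config$n_cis_100k)
                    sample((w[1] + 5000):(w[2] - 5000),
                           config$n_cis_100k))
    dist_sign <- rep_len(c(1L, -1L), n_cis)
    cis_pairs <- data.frame(
      lnc_id = c_lnc, gene_id = sub("\\.t1$", "", c_gene),
      gene_tx = c_gene, distance = dist_sign * dist_mag,
      window_class = rep(paste0(w / 1000, "k"),
                         c(config$n_cis_10k, config$n_cis_100k)),
      stringsAsFactors = FALSE)
  }

  ## ---- differential expression plan -------------------------------------
  lfc_mag <- function(n) abs(stats::rnorm(n, config$lfc_mean,
                                          config$lfc_sd))
  lfc <- stats::setNames(numeric(length(tx_ids)), tx_ids)
  mir_lfc <- stats::setNames(numeric(config$n_mirna), names(mirna_seqs))
  if (!is.null(triads)) {
    sgn <- ifelse(triads$pattern == "up-down-up", 1, -1)
    shared_mag <- lfc_mag(nrow(triads))
    lfc[triads$lnc_id] <- sgn * shared_mag
    lfc[triads$mrna_id] <- sgn * shared_mag   # equal LFC: noise-free r = 1
    mir_lfc[triads$mirna_id] <- -sgn * lfc_mag(nrow(triads))
  }
  if (!is.null(extra_trans)) {
    mag <- lfc_mag(nrow(extra_trans)) *
      sample(c(-1, 1), nrow(extra_trans), replace = TRUE)
    lfc[extra_trans$lnc_id] <- mag
    lfc[extra_trans$gene_id] <- mag
  }
  fill_de <- function(pool, lfc_vec) {
    target <- round(config$de_fraction * length(pool))
    extra <- target - sum(lfc_vec[pool] != 0)
    if (extra > 0) {
      free <- pool[lfc_vec[pool] == 0]
      chosen <- resample(free, min(extra, length(free)))
      lfc_vec[chosen] <- lfc_mag(length(chosen)) *
        sample(c(-1, 1), length(chosen), replace = TRUE)
    }
    lfc_vec
  }
  lfc <- fill_de(ids$coding, lfc)
  lfc <- fill_de(lnc_ids, lfc)
  mir_lfc <- fill_de(names(mirna_seqs), mir_lfc)

  ## ---- transcript structures and genome layout ---------------------------
  lens <- stats::setNames(integer(length(tx_ids)), tx_ids)
  nex <- stats::setNames(integer(length(tx_ids)), tx_ids)
  for (tid in tx_ids) {
    cls <- tx_class[[tid]]
    if (cls == "decoy_single_exon") {
      lens[tid] <- config$seq_len_lnc; nex[tid] <- 1L
    } else if (cls == "decoy_short") {
      # one decoy sits exactly on the strict 200 bp boundary
      lens[tid] <- if (tid == ids$decoy_short[1]) 200L else
        sample(150:199, 1)
      nex[tid] <- 2L
    } else if (cls %in% c("coding", "decoy_coding_like")) {
      lens[tid] <- config$seq_len_coding; nex[tid] <- sample(2:4, 1)
    } else {
      lens[tid] <- config$seq_len_lnc; nex[tid] <- sample(2:4, 1)
    }
  }

  cis_first <- if (is.null(cis_pairs)) character(0) else
    ifelse(cis_pairs$distance > 0, cis_pairs$lnc_id, cis_pairs$gene_tx)
  cis_second <- if (is.null(cis_pairs)) character(0) else
    ifelse(cis_pairs$distance > 0, cis_pairs$gene_tx, cis_pairs$lnc_id)
  models <- list()
  cursor <- 10000L
  for (tid in tx_ids) {
    if (tid %in% cis_second) next   # placed together with its partner
    exl <- split_exons(lens[tid], nex[tid])
    exons <- place_exons(cursor, exl)
    biotype <- if (tx_class[[tid]] == "coding") "coding"
      else if (tx_class[[tid]] == "known_lnc") "known_lncRNA"
      else "unknown"
    models[[tid]] <- TranscriptModel(tid, gene_of[[tid]], config$chrom,
                                     sample(c("+", "-"), 1), exons,
                                     biotype)
    unit_end <- max(exons[, "end"])
    if (tid %in% cis_first) {
      i <- which(cis_first == tid)
      partner <- cis_second[i]
      gap <- abs(cis_pairs$distance[i])
      exl2 <- split_exons(lens[partner], nex[partner])
      exons2 <- place_exons(unit_end + gap, exl2)
      biotype2 <- if (tx_class[[partner]] == "coding") "coding"
        else if (tx_class[[partner]] == "known_lnc") "known_lncRNA"
        else "unknown"
      models[[partner]] <- TranscriptModel(partner, gene_of[[partner]],
                                           config$chrom,
                                           sample(c("+", "-"), 1),
                                           exons2, biotype2)
      unit_end <- max(exons2[, "end"])
    }
    cursor <- unit_end + config$intergenic_gap + sample(0:50000, 1)
  }
  models <- models[tx_ids]

  ## ---- sequences ---------------------------------------------------------
  seqs <- stats::setNames(character(length(tx_ids)), tx_ids)
  site_rec <- list()
  planted_site_of <- stats::setNames(rep(NA_character_, length(tx_ids)),
                                     tx_ids)
  if (!is.null(triads))
    planted_site_of[c(triads$lnc_id, triads$mrna_id)] <-
      c(triads$mirna_id, triads$mirna_id)
  for (tid in tx_ids) {
    cls <- tx_class[[tid]]
    mir <- planted_site_of[[tid]]
    for (attempt in 1:200) {
      if (cls %in% c("coding", "decoy_coding_like")) {
        cs <- clean_coding_seq(lens[tid], forbidden, config$orf_codons)
        s <- cs$seq
        plant_region <- c(cs$orf_end + 1L, lens[tid])
      } else {
        s <- clean_random_seq(lens[tid], forbidden, max_orf = 100L)
        plant_region <- c(1L, lens[tid])
      }
      if (is.na(mir)) { seqs[tid] <- s; break }
      planted <- plant_seed_site(s, mirna_seqs[[mir]], "8mer",
                                 region = plant_region)
      # the planted site must not create >= 6mer matches for any other
      # catalog miRNA (keeps shared MREs strictly planted) nor, in a
      # noncoding transcript, complete a threshold-length ORF
      others <- setdiff(names(mirna_seqs), mir)
      stray <- any(vapply(forbidden[others], grepl, TRUE,
                          x = planted$seq, fixed = TRUE))
      if (!(cls %in% c("coding", "decoy_coding_like")) &&
          orf_coding_potential(planted$seq)$score >= 100L)
        stray <- TRUE
      if (!stray) {
        seqs[tid] <- planted$seq
        site_rec[[tid]] <- data.frame(
          target_id = tid, mirna_id = mir, start = planted$start,
          site_type = "8mer", stringsAsFactors = FALSE)
        break
      }
      if (attempt == 200) stop("could not plant a clean site in ", tid)
    }
  }
  planted_sites <- if (length(site_rec))
    do.call(rbind, c(site_rec, list(make.row.names = FALSE))) else
    data.frame(target_id = character(), mirna_id = character(),
               start = integer(), site_type = character(),
               stringsAsFactors = FALSE)

  ## ---- expression --------------------------------------------------------
  nrep <- config$n_samples_per_group
  samples <- c(sprintf("anagen_%d", seq_len(nrep)),
               sprintf("catagen_%d", seq_len(nrep)))
  design <- stats::setNames(rep(c("anagen", "catagen"), each = nrep),
                            samples)
  is_cat <- as.numeric(design == "catagen")

  mu <- stats::setNames(numeric(length(tx_ids)), tx_ids)
  for (tid in tx_ids) {
    mu[tid] <- switch(tx_class[[tid]],
                      coding = stats::runif(1, 2, 8),
                      decoy_coding_like = stats::runif(1, 2, 8),
                      decoy_low_expr = log2(0.05),
                      stats::runif(1, 1, 6))
  }
  log2_expr <- outer(lfc[tx_ids], is_cat) + mu[tx_ids]
  rownames(log2_expr) <- tx_ids
  colnames(log2_expr) <- samples
  eps <- matrix(stats::rnorm(length(log2_expr), 0, config$noise_sd),
                nrow(log2_expr), dimnames = dimnames(log2_expr))
  if (!is.null(trans_pairs)) {
    resid_sd <- config$trans_resid_frac * config$noise_sd
    for (i in seq_len(nrow(trans_pairs))) {
      z <- stats::rnorm(length(samples), 0, config$latent_sd)
      log2_expr[trans_pairs$lnc_id[i], ] <-
        log2_expr[trans_pairs$lnc_id[i], ] + z
      log2_expr[trans_pairs$gene_id[i], ] <-
        log2_expr[trans_pairs$gene_id[i], ] + z
      # partners share their noise up to a small residual: tight
      # co-regulation, collapsing to exact proportionality at noise 0
      eps[trans_pairs$gene_id[i], ] <- eps[trans_pairs$lnc_id[i], ] +
        stats::rnorm(length(samples), 0, resid_sd)
    }
  }
  fpkm_vals <- 2^(log2_expr + eps)
  fpkm <- ExpressionMatrix(fpkm_vals, "FPKM", design)

  mir_mu <- stats::setNames(stats::runif(config$n_mirna, 4, 10),
                            names(mirna_seqs))
  log2_tpm <- outer(mir_lfc, is_cat) + mir_mu
  colnames(log2_tpm) <- samples
  tpm_vals <- 2^(log2_tpm +
                   matrix(stats::rnorm(length(log2_tpm), 0,
                                       config$noise_sd),
                          nrow(log2_tpm)))
  tpm <- ExpressionMatrix(tpm_vals, "TPM", design)

  ## ---- gene sets ---------------------------------------------------------
  # gene sets tile the coding genes, DE-planted genes first, so the
  # leading term(s) are genuinely over-represented among DE genes
  coding_order <- ids$coding[order(lfc[ids$coding] == 0, ids$coding)]
  coding_genes <- sub("\\.t1$", "", coding_order)
  n_terms <- max(1L, ceiling(length(coding_genes) / 35))
  term_of <- rep(sprintf("SET%02d", seq_len(n_terms)), each = 35,
                 length.out = length(coding_genes))
  gene_sets <- data.frame(term = term_of, gene = coding_genes,
                          stringsAsFactors = FALSE)
  gene_sets <- gene_sets[order(gene_sets$term, gene_sets$gene), ]

  ## ---- manifest ----------------------------------------------------------
  tt <- transcript_table(models)
  features <- data.frame(
    feature_id = tx_ids, class = unname(tx_class[tx_ids]),
    gene_id = unname(gene_of[tx_ids]), mu_log2 = unname(mu[tx_ids]),
    lfc = unname(lfc[tx_ids]), de = unname(lfc[tx_ids] != 0),
    direction = ifelse(lfc[tx_ids] > 0, "up",
                       ifelse(lfc[tx_ids] < 0, "down", "none")),
    mean_anagen = unname(2^mu[tx_ids]),
    mean_catagen = unname(2^(mu[tx_ids] + lfc[tx_ids])),
    length = tt$length[match(tx_ids, tt$transcript_id)],
    n_exons = tt$n_exons[match(tx_ids, tt$transcript_id)],
    stringsAsFactors = FALSE)
  mirnas <- data.frame(
    feature_id = names(mirna_seqs), lfc = unname(mir_lfc),
    de = unname(mir_lfc != 0),
    direction = ifelse(mir_lfc > 0, "up",
                       ifelse(mir_lfc < 0, "down", "none")),
    mean_anagen = unname(2^mir_mu),
    mean_catagen = unname(2^(mir_mu + mir_lfc)),
    stringsAsFactors = FALSE)
  manifest <- list(
    config = unclass(config), features = features, mirnas = mirnas,
    cis_pairs = if (is.null(cis_pairs)) data.frame() else cis_pairs,
    trans_pairs = if (is.null(trans_pairs)) data.frame() else {
      # expected Pearson r between partners: shared variance (group shift
      # over a balanced 3v3 design has indicator variance 0.3, plus latent
      # and shared noise) against the gene partner's residual
      shared <- lfc[trans_pairs$lnc_id]^2 * 0.3 + config$latent_sd^2 +
        config$noise_sd^2
      resid2 <- (config$trans_resid_frac * config$noise_sd)^2
      data.frame(trans_pairs,
                 target_r = unname(sqrt(shared / (shared + resid2))),
                 stringsAsFactors = FALSE)
    },
    triads = if (is.null(triads)) data.frame() else
      merge(merge(triads,
                  stats::setNames(planted_sites[c("target_id", "start")],
                                  c("lnc_id", "lnc_site_start")),
                  by = "lnc_id"),
            stats::setNames(planted_sites[c("target_id", "start")],
                            c("mrna_id", "mrna_site_start")),
            by = "mrna_id")[, c("lnc_id", "mirna_id", "mrna_id",
                                "pattern", "lnc_site_start",
                                "mrna_site_start")],
    planted_sites = planted_sites)

  result <- list(transcripts = models, transcript_seqs = seqs,
                 mirna_seqs = mirna_seqs, fpkm = fpkm, tpm = tpm,
                 design = design, coding_ids = ids$coding,
                 known_lnc_ids = ids$known_lnc, gene_sets = gene_sets,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_gtf(models, p("annotation.gtf"))
    write_fasta(seqs, p("transcripts.fa"))
    write_fasta(mirna_seqs, p("mirnas.fa"))
    write_expression_table(fpkm, p("expression_fpkm.tsv"))
    write_expression_table(tpm, p("expression_tpm.tsv"))
    write_design(design, p("design.tsv"))
    writeLines(ids$coding, p("coding_ids.txt"))
    writeLines(ids$known_lnc, p("known_lncrna_ids.txt"))
    writeLines(names(mirna_seqs), p("known_mirna_ids.txt"))
    utils::write.table(gene_sets, p("gene_sets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
    result$paths <- stats::setNames(
      vapply(c("annotation.gtf", "transcripts.fa", "mirnas.fa",
               "expression_fpkm.tsv", "expression_tpm.tsv", "design.tsv",
               "coding_ids.txt", "known_lncrna_ids.txt",
               "known_mirna_ids.txt", "gene_sets.tsv", "manifest.json"),
             p, ""),
      c("gtf", "transcripts_fa", "mirnas_fa", "fpkm", "tpm", "design",
        "coding_ids", "known_lnc_ids", "known_mirna_ids", "gene_sets",
        "manifest"))
  }
  result
}
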