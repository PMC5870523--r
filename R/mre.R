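#' Canonical seed-site motifs for a miRNA
#'
#' Builds the four canonical target-site motifs from a miRNA sequence in
#' the TargetScan convention, all in the DNA alphabet (U normalized to T).
#' With seed nucleotides m2-m8 (and m2-m7 for the 6-nt core):
#' * `8mer`: reverse complement of m2-m8 followed by a literal `A`;
#' * `7mer-m8`: reverse complement of m2-m8;
#' * `7mer-A1`: reverse complement of m2-m7 followed by a literal `A`;
#' * `6mer`: reverse complement of m2-m7.
#' The `A` anchor opposite miRNA position 1 is a literal A in the target
#' regardless of the miRNA's first nucleotide.
#'
#' @param mirna_seq miRNA sequence (>= 8 nt; RNA or DNA alphabet).
#' @return Named character vector of motifs, in priority order
#'   `8mer > 7mer-m8 > 7mer-A1 > 6mer`.
#' @export
seed_motifs <- function(mirna_seq) {
  m <- chartr("U", "T", toupper(mirna_seq))
  if (nchar(m) < 8) stop("miRNA sequence shorter than 8 nt")
  rc28 <- revcomp(substr(m, 2, 8))
  rc27 <- revcomp(substr(m, 2, 7))
  c(`8mer` = paste0(rc28, "A"),
    `7mer-m8` = rc28,
    `7mer-A1` = paste0(rc27, "A"),
    `6mer` = rc27)
}

# all (overlapping) 1-based start positions of fixed `motif` in `seq`
motif_starts <- function(motif, seq) {
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq))
  Biostrings::start(hits)
}

#' Predict canonical miRNA seed sites on a target sequence
#'
#' Scans the full target sequence for the four canonical site types.
#' Each target position is reported at most once, with its
#' highest-priority type (`8mer > 7mer-m8 > 7mer-A1 > 6mer`); overlapping
#' sites at distinct positions are all reported. Matching is performed in
#' the DNA alphabet, so U/T representation of either input is irrelevant.
#'
#' @param mirna_seq miRNA sequence (>= 8 nt).
#' @param target_seq target (lncRNA or mRNA) sequence.
#' @return data.frame with columns `start` (1-based position of the first
#'   site nucleotide on the target) and `site_type`; zero rows if no match.
#' @export
seed_sites <- function(mirna_seq, target_seq) {
  target <- chartr("U", "T", toupper(target_seq))
  motifs <- seed_motifs(mirna_seq)
  out_start <- integer(0)
  out_type <- character(0)
  for (type in names(motifs)) {
    st <- motif_starts(motifs[[type]], target)
    st <- setdiff(st, out_start)   # keep highest-priority type per position
    out_start <- c(out_start, st)
    out_type <- c(out_type, rep(type, length(st)))
  }
  ord <- order(out_start)
  data.frame(start = out_start[ord], site_type = out_type[ord],
             stringsAsFactors = FALSE)
}

#' Scan a miRNA catalog against a set of target sequences
#'
#' @param mirna_seqs named character vector of miRNA sequences.
#' @param target_seqs named character vector of target sequences.
#' @return data.frame with columns `mirna_id`, `target_id`, `start`,
#'   `site_type`, one row per predicted site.
#' @export
scan_seed_sites <- function(mirna_seqs, target_seqs) {
  stopifnot(!is.null(names(mirna_seqs)), !is.null(names(target_seqs)))
  empty <- data.frame(mirna_id = character(), target_id = character(),
                      start = integer(), site_type = character(),
                      stringsAsFactors = FALSE)
  if (!length(mirna_seqs) || !length(target_seqs)) return(empty)
  targets <- Biostrings::DNAStringSet(
    chartr("U", "T", toupper(target_seqs)))
  res <- list()
  for (mi in names(mirna_seqs)) {
    motifs <- seed_motifs(mirna_seqs[[mi]])
    seen <- character(0)            # target\rstart keys already claimed
    for (type in names(motifs)) {   # priority order
      hits <- Biostrings::vmatchPattern(motifs[[type]], targets)
      st <- Biostrings::startIndex(hits)
      tgt <- rep(names(target_seqs), lengths(st))
      start <- unlist(st, use.names = FALSE)
      if (!length(start)) next
      key <- paste(tgt, start, sep = "\r")
      new <- !key %in% seen
      seen <- c(seen, key[new])
      if (any(new))
        res[[length(res) + 1L]] <- data.frame(
          mirna_id = mi, target_id = tgt[new], start = start[new],
          site_type = type, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out <- out[order(out$mirna_id, out$target_id, out$start), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Detect shared miRNA response elements between lncRNAs and mRNAs
#'
#' A shared MRE -- the ceRNA precondition -- is a miRNA with at least one
#' predicted seed site on a lncRNA and at least one on an mRNA.
#'
#' @param lnc_sites data.frame of sites on lncRNAs (as from
#'   [scan_seed_sites()], `target_id` = lncRNA id).
#' @param mrna_sites data.frame of sites on mRNAs.
#' @return data.frame with one row per (miRNA, lncRNA, mRNA) trio carrying
#'   sites on both molecules: `mirna_id`, `lnc_id`, `mrna_id`,
#'   `n_lnc_sites`, `n_mrna_sites`, `lnc_site_types`, `mrna_site_types`
#'   (comma-joined, position-ordered).
#' @export
shared_mres <- function(lnc_sites, mrna_sites) {
  empty <- data.frame(mirna_id = character(), lnc_id = character(),
                      mrna_id = character(), n_lnc_sites = integer(),
                      n_mrna_sites = integer(), lnc_site_types = character(),
                      mrna_site_types = character(), stringsAsFactors = FALSE)
  if (!nrow(lnc_sites) || !nrow(mrna_sites)) return(empty)
  agg <- function(df) {
    df <- df[order(df$mirna_id, df$target_id, df$start), ]
    key <- paste(df$mirna_id, df$target_id, sep = "\r")
    data.frame(mirna_id = df$mirna_id[!duplicated(key)],
               target_id = df$target_id[!duplicated(key)],
               n_sites = as.integer(table(key)[unique(key)]),
               site_types = vapply(split(df$site_type, key)[unique(key)],
                                   paste, "", collapse = ","),
               stringsAsFactors = FALSE)
  }
  la <- agg(lnc_sites)
  ma <- agg(mrna_sites)
  out <- merge(la, ma, by = "mirna_id", suffixes = c("_lnc", "_mrna"))
  if (!nrow(out)) return(empty)
  out <- data.frame(
    mirna_id = out$mirna_id, lnc_id = out$target_id_lnc,
    mrna_id = out$target_id_mrna, n_lnc_sites = out$n_sites_lnc,
    n_mrna_sites = out$n_sites_mrna, lnc_site_types = out$site_types_lnc,
    mrna_site_types = out$site_types_mrna, stringsAsFactors = FALSE)
  out[order(out$mirna_id, out$lnc_id, out$mrna_id), , drop = FALSE]
}
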