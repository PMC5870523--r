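# Independent brute-force oracles used across the suite. These are written
# from the definitions, deliberately not sharing code paths with the
# package implementation.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# naive all-substring seed-site scan: walk every position, compare the
# literal motif strings in priority order
oracle_seed_sites <- function(mirna, target) {
  m <- chartr("U", "T", toupper(mirna))
  t <- chartr("U", "T", toupper(target))
  rc28 <- oracle_revcomp(substr(m, 2, 8))
  rc27 <- oracle_revcomp(substr(m, 2, 7))
  motifs <- list(`8mer` = paste0(rc28, "A"), `7mer-m8` = rc28,
                 `7mer-A1` = paste0(rc27, "A"), `6mer` = rc27)
  starts <- integer(0); types <- character(0)
  for (pos in seq_len(nchar(t))) {
    for (ty in names(motifs)) {
      k <- nchar(motifs[[ty]])
      if (pos + k - 1 <= nchar(t) &&
          substr(t, pos, pos + k - 1) == motifs[[ty]]) {
        starts <- c(starts, pos); types <- c(types, ty)
        break
      }
    }
  }
  data.frame(start = starts, site_type = types, stringsAsFactors = FALSE)
}

# independent 3-frame ORF scan: codon-by-codon state machine
oracle_orf_score <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  best <- 0
  for (f in 0:2) {
    i <- 1 + f
    open_at <- NA
    while (i + 2 <= nchar(s)) {
      codon <- substr(s, i, i + 2)
      if (is.na(open_at) && codon == "ATG") open_at <- i
      if (!is.na(open_at) && codon %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, (i - open_at) / 3)
        open_at <- NA
        # a later ATG before this stop cannot beat the one just closed,
        # but ATGs after the stop can: keep walking
      }
      i <- i + 3
    }
  }
  best
}

# quadratic all-pairs cis scan over locus tables (transcript span for
# lncRNAs, merged span per gene for coding)
oracle_cis_pairs <- function(lnc_tab, gene_tab, windows) {
  windows <- sort(windows)
  genes <- do.call(rbind, lapply(split(gene_tab, gene_tab$gene_id),
                                 function(d) data.frame(
                                   gene_id = d$gene_id[1],
                                   chrom = d$chrom[1],
                                   start = min(d$start),
                                   end = max(d$end))))
  out <- NULL
  for (i in seq_len(nrow(lnc_tab))) {
    for (j in seq_len(nrow(genes))) {
      if (lnc_tab$chrom[i] != genes$chrom[j]) next
      if (genes$start[j] > lnc_tab$end[i]) {
        d <- genes$start[j] - lnc_tab$end[i]
      } else if (genes$end[j] < lnc_tab$start[i]) {
        d <- genes$end[j] - lnc_tab$start[i]
      } else d <- 0
      if (abs(d) > max(windows)) next
      w <- windows[which(abs(d) <= windows)[1]]
      out <- rbind(out, data.frame(
        lnc_id = lnc_tab$transcript_id[i], gene_id = genes$gene_id[j],
        distance = d, window = w, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(data.frame(lnc_id = character(),
                                      gene_id = character(),
                                      distance = numeric(),
                                      window = numeric()))
  out[order(out$lnc_id, out$gene_id), , drop = FALSE]
}

# exact hypergeometric upper tail by the combinatorial sum
oracle_hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
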