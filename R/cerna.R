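#' Classify the expression pattern of a lncRNA-miRNA-mRNA trio
#'
#' Catagen-vs-anagen direction triple -> pattern class. Exactly two of the
#' eight combinations are ceRNA-concordant: (up, down, up) ->
#' `"up-down-up"` and (down, up, down) -> `"down-up-down"`; every other
#' combination is `"discordant"`.
#'
#' @param dir_lnc,dir_mirna,dir_mrna directions, each `"up"` or `"down"`.
#' @return `"up-down-up"`, `"down-up-down"` or `"discordant"`.
#' @export
classify_pattern <- function(dir_lnc, dir_mirna, dir_mrna) {
  dirs <- c(dir_lnc, dir_mirna, dir_mrna)
  if (!all(dirs %in% c("up", "down")))
    stop("directions must be 'up' or 'down', got: ",
         paste(dirs, collapse = ", "))
  if (dir_lnc == "up" && dir_mirna == "down" && dir_mrna == "up")
    "up-down-up"
  else if (dir_lnc == "down" && dir_mirna == "up" && dir_mrna == "down")
    "down-up-down"
  else "discordant"
}

#' Assemble ceRNA triads from DE calls, shared MREs and correlations
#'
#' A triad (lncRNA decoy, miRNA center, mRNA target) is emitted iff
#' (i) all three molecules are differentially expressed, (ii) a shared
#' miRNA response element exists for the trio, and (iii) the lncRNA-mRNA
#' pair passed the trans co-expression screen, with r > 0 when
#' `require_positive_lnc_mrna_r` is set (the ceRNA hypothesis demands
#' positive decoy-target co-expression). Discordant-pattern triads are
#' suppressed unless `keep_discordant`.
#'
#' @param de_lnc,de_mirna,de_mrna DE-called tables (from [call_de()]) in
#'   the same catagen-vs-anagen orientation; columns `feature_id`,
#'   `direction`.
#' @param shared data.frame of shared MREs (from [shared_mres()]).
#' @param correlations retained trans-screen records (from
#'   [trans_targets()]); columns `lnc_id`, `gene_id`, `r`.
#' @param require_positive_lnc_mrna_r require r > 0 (default `TRUE`).
#' @param keep_discordant also emit discordant triads (default `FALSE`).
#' @param lnc_universe,mirna_universe,mrna_universe optional id vectors of
#'   all tested molecules; a shared-MRE molecule absent from its universe
#'   is an error (it was never tested for DE).
#' @return data.frame of triads: `lnc_id`, `mirna_id`, `mrna_id`,
#'   `pattern`, `lnc_mrna_r`, `n_lnc_sites`, `n_mrna_sites`,
#'   `lnc_site_types`, `mrna_site_types`.
#' @export
build_triads <- function(de_lnc, de_mirna, de_mrna, shared, correlations,
                         require_positive_lnc_mrna_r = TRUE,
                         keep_discordant = FALSE,
                         lnc_universe = NULL, mirna_universe = NULL,
                         mrna_universe = NULL) {
  empty <- data.frame(lnc_id = character(), mirna_id = character(),
                      mrna_id = character(), pattern = character(),
                      lnc_mrna_r = numeric(), n_lnc_sites = integer(),
                      n_mrna_sites = integer(), lnc_site_types = character(),
                      mrna_site_types = character(), stringsAsFactors = FALSE)
  if (!nrow(shared)) return(empty)
  check_universe <- function(ids, universe, what) {
    if (is.null(universe)) return(invisible())
    bad <- setdiff(ids, universe)
    if (length(bad))
      stop("shared-MRE ", what, " absent from DE tables: ",
           paste(bad, collapse = ", "))
  }
  check_universe(shared$lnc_id, lnc_universe, "lncRNA(s)")
  check_universe(shared$mirna_id, mirna_universe, "miRNA(s)")
  check_universe(shared$mrna_id, mrna_universe, "mRNA(s)")

  dir_of <- function(de) stats::setNames(de$direction, de$feature_id)
  dl <- dir_of(de_lnc); dmi <- dir_of(de_mirna); dm <- dir_of(de_mrna)
  keep <- shared$lnc_id %in% names(dl) & shared$mirna_id %in% names(dmi) &
    shared$mrna_id %in% names(dm)
  cand <- shared[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)

  corr_key <- paste(correlations$lnc_id, correlations$gene_id, sep = "\r")
  corr_r <- stats::setNames(correlations$r, corr_key)
  cand_key <- paste(cand$lnc_id, cand$mrna_id, sep = "\r")
  has_corr <- cand_key %in% names(corr_r)
  r <- ifelse(has_corr, corr_r[cand_key], NA_real_)
  ok <- has_corr & (!require_positive_lnc_mrna_r | r > 0)
  cand <- cand[ok, , drop = FALSE]
  r <- r[ok]
  if (!nrow(cand)) return(empty)

  pattern <- mapply(classify_pattern, dl[cand$lnc_id], dmi[cand$mirna_id],
                    dm[cand$mrna_id], USE.NAMES = FALSE)
  out <- data.frame(lnc_id = cand$lnc_id, mirna_id = cand$mirna_id,
                    mrna_id = cand$mrna_id, pattern = pattern,
                    lnc_mrna_r = unname(r),
                    n_lnc_sites = cand$n_lnc_sites,
                    n_mrna_sites = cand$n_mrna_sites,
                    lnc_site_types = cand$lnc_site_types,
                    mrna_site_types = cand$mrna_site_types,
                    stringsAsFactors = FALSE)
  if (!keep_discordant)
    out <- out[out$pattern != "discordant", , drop = FALSE]
  out <- out[order(out$mirna_id, out$lnc_id, out$mrna_id), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Gene-centric triad report
#'
#' One row per target mRNA gene, listing its ceRNA lncRNAs split by
#' regulatory mode (cis column: lncRNAs also genomically paired with the
#' gene; trans column: the remaining co-expression-only lncRNAs) and its
#' miRNAs; entries deduplicated and lexicographically sorted.
#'
#' @param triads data.frame from [build_triads()].
#' @param cis_pairs optional data.frame from [cis_targets()] annotating
#'   which (lncRNA, gene) pairs are genomic neighbours.
#' @param transcript_gene_map optional named character vector mapping mRNA
#'   transcript ids to gene ids (default: identity).
#' @return data.frame with columns `gene`, `lnc_in_cis`, `lnc_in_trans`,
#'   `mirnas` (comma-joined, possibly empty strings).
#' @export
triad_table <- function(triads, cis_pairs = NULL,
                        transcript_gene_map = NULL) {
  if (!nrow(triads))
    return(data.frame(gene = character(), lnc_in_cis = character(),
                      lnc_in_trans = character(), mirnas = character(),
                      stringsAsFactors = FALSE))
  gene <- if (is.null(transcript_gene_map)) triads$mrna_id else {
    unmapped <- setdiff(triads$mrna_id, names(transcript_gene_map))
    if (length(unmapped))
      stop("mRNA transcript(s) without gene mapping: ",
           paste(unmapped, collapse = ", "))
    unname(transcript_gene_map[triads$mrna_id])
  }
  cis_key <- if (is.null(cis_pairs)) character() else
    paste(cis_pairs$lnc_id, cis_pairs$gene_id, sep = "\r")
  rows <- lapply(split(seq_len(nrow(triads)), gene), function(ix) {
    g <- gene[ix[1]]
    lncs <- sort(unique(triads$lnc_id[ix]))
    in_cis <- lncs[paste(lncs, g, sep = "\r") %in% cis_key]
    data.frame(gene = g,
               lnc_in_cis = paste(in_cis, collapse = ","),
               lnc_in_trans = paste(setdiff(lncs, in_cis), collapse = ","),
               mirnas = paste(sort(unique(triads$mirna_id[ix])),
                              collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$gene), , drop = FALSE]
}
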