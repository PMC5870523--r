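#' Longest-ORF coding-potential score
#'
#' Built-in coding-potential predictor: the score is the length, in
#' codons, of the longest open reading frame (ATG to the codon preceding
#' an in-frame stop) over the three forward frames of the transcript
#' sequence (transcript sequences are sense-strand by construction, so no
#' reverse-strand scan). A sequence with no ATG-led ORF scores 0. The call
#' is `"coding"` iff the score reaches `threshold` codons.
#'
#' @param seq transcript sequence (DNA alphabet; U tolerated).
#' @param threshold minimum ORF length in codons for a coding call
#'   (default 100).
#' @return list with elements `score` (codons) and `call`
#'   (`"coding"`/`"noncoding"`).
#' @export
orf_coding_potential <- function(seq, threshold = 100) {
  s <- chartr("U", "T", toupper(seq))
  n <- nchar(s)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    starts <- seq.int(1 + f, n - 2, by = 3)
    if (length(starts) == 0 || starts[1] > n - 2) next
    codons <- substring(s, starts, starts + 2)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    if (!length(atg) || !length(stp)) next
    # next in-frame stop strictly after each ATG
    nxt <- stp[findInterval(atg, stp) + 1L]
    ok <- !is.na(nxt)
    if (any(ok)) best <- max(best, nxt[ok] - atg[ok])
  }
  list(score = as.integer(best),
       call = if (best >= threshold) "coding" else "noncoding")
}

#' Build an ORF-based coding-potential predictor
#'
#' Returns a predictor closure suitable for [filter_cascade()]: given
#' transcript ids it returns a named vector of `"coding"`/`"noncoding"`
#' calls computed by [orf_coding_potential()] on the supplied sequences.
#'
#' @param seqs named character vector of transcript sequences.
#' @param threshold ORF-length threshold in codons.
#' @return function(ids) -> named character vector of calls.
#' @export
make_orf_predictor <- function(seqs, threshold = 100) {
  force(seqs); force(threshold)
  function(ids) {
    missing <- setdiff(ids, names(seqs))
    if (length(missing))
      stop("no sequence for transcript(s): ", paste(missing, collapse = ", "))
    vapply(seqs[ids], function(s) orf_coding_potential(s, threshold)$call, "")
  }
}

#' Intersect noncoding calls across predictors
#'
#' @param calls list of named character vectors of
#'   `"coding"`/`"noncoding"` calls, one per predictor, over the same ids.
#' @return Character vector of ids called noncoding by every predictor.
#' @export
intersect_noncoding <- function(calls) {
  if (!length(calls)) stop("need at least one predictor's calls")
  Reduce(intersect, lapply(calls, function(v) names(v)[v == "noncoding"]))
}

#' Five-criterion novel-lncRNA identification cascade
#'
#' Applies, in order: (1) keep transcripts with at least `exon_min` exons;
#' (2) keep spliced length strictly greater than `length_min` bp; (3) set
#' known lncRNAs aside as the known-lncRNA catalog, only unknown
#' transcripts continue; (4) keep transcripts whose maximum FPKM across
#' samples reaches `fpkm_min`; (5) keep transcripts called noncoding by
#' every supplied coding-potential predictor (intersection). Transcripts
#' failing predictor unanimity without being called coding by all
#' predictors are reported separately as transcripts of uncertain coding
#' potential (TUCP).
#'
#' @param transcripts list of `TranscriptModel`.
#' @param known_lnc_ids character vector of known-lncRNA transcript ids.
#' @param expr [ExpressionMatrix()] (FPKM) covering every transcript.
#' @param predictors list of predictor closures (see
#'   [make_orf_predictor()]); at least one.
#' @param exon_min minimum exon count (default 2).
#' @param length_min spliced length must exceed this, strict (default 200).
#' @param fpkm_min minimum of the per-transcript maximum FPKM (default 0.5).
#' @return list with elements:
#'   * `novel_lnc_ids`: transcript ids surviving all five steps;
#'   * `known_lnc_ids`: known lncRNAs set aside at step 3 (of those
#'     surviving steps 1-2);
#'   * `tucp_ids`: uncertain-coding-potential transcripts;
#'   * `report`: data.frame funnel with `step`, `description`,
#'     `n_surviving`;
#'   * `surviving`: list of surviving id sets per step;
#'   * `predictor_calls`: ids x predictors character matrix of calls for
#'     step-4 survivors.
#' @export
filter_cascade <- function(transcripts, known_lnc_ids, expr, predictors,
                           exon_min = 2, length_min = 200, fpkm_min = 0.5) {
  if (!length(predictors)) stop("need at least one coding-potential predictor")
  tt <- transcript_table(transcripts)
  missing_expr <- setdiff(tt$transcript_id, rownames(expr$values))
  if (length(missing_expr))
    stop("transcript(s) missing from expression matrix: ",
         paste(missing_expr, collapse = ", "))

  s0 <- tt$transcript_id
  s1 <- tt$transcript_id[tt$n_exons >= exon_min]
  s2 <- intersect(s1, tt$transcript_id[tt$length > length_min])
  known_kept <- intersect(s2, known_lnc_ids)
  s3 <- setdiff(s2, known_lnc_ids)
  max_fpkm <- apply(expr$values[s3, , drop = FALSE], 1, max)
  s4 <- s3[max_fpkm >= fpkm_min]

  calls <- lapply(predictors, function(p) p(s4))
  if (is.null(names(calls)) || any(!nzchar(names(calls))))
    names(calls) <- paste0("predictor", seq_along(calls))
  s5 <- intersect(s4, intersect_noncoding(calls))
  all_coding <- Reduce(intersect,
                       lapply(calls, function(v) names(v)[v == "coding"]))
  tucp <- setdiff(s4, union(s5, all_coding))

  surviving <- list(input = s0, step1_exons = s1, step2_length = s2,
                    step3_unknown = s3, step4_expression = s4,
                    step5_noncoding = s5)
  report <- data.frame(
    step = c("input", "step1_exons", "step2_length", "step3_unknown",
             "step4_expression", "step5_noncoding"),
    description = c(
      "all assembled transcripts",
      sprintf("no fewer than %d exons", exon_min),
      sprintf("spliced length > %d bp", length_min),
      "known lncRNAs set aside; unknown transcripts continue",
      sprintf("max FPKM across samples >= %g", fpkm_min),
      "called noncoding by all coding-potential predictors"),
    n_surviving = unname(vapply(surviving, length, 0L)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(novel_lnc_ids = s5, known_lnc_ids = known_kept, tucp_ids = tucp,
       report = report, surviving = surviving,
       predictor_calls = do.call(cbind, calls))
}
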