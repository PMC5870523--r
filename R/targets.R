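#' Cis target prediction: coding genes near lncRNA loci
#'
#' For each lncRNA locus (min exon start to max exon end of the
#' transcript), reports coding genes whose gene span (union of the gene's
#' transcript spans) lies within or overlaps `[locus_start - w,
#' locus_end + w]` for each window size `w`. Both upstream and downstream
#' are searched; strand is ignored for distance. Distance is 0 for
#' overlapping spans, otherwise the gap between nearest span edges, signed
#' positive when the gene lies downstream (higher coordinates) of the
#' lncRNA on the genome axis and negative upstream. Each pair is reported
#' once with the smallest window class containing it.
#'
#' @param lnc_models list of `TranscriptModel` for lncRNA transcripts.
#' @param gene_models list of `TranscriptModel` for coding transcripts.
#' @param windows numeric vector of window half-widths in bp.
#' @return data.frame with columns `lnc_id`, `gene_id`, `distance`,
#'   `window` (smallest containing window size, bp) and `window_class`
#'   (e.g. `"10k"`).
#' @export
cis_targets <- function(lnc_models, gene_models,
                        windows = c(10000, 100000)) {
  windows <- sort(windows)
  lt <- transcript_table(lnc_models)
  gt <- transcript_table(gene_models)
  # gene span = union of the gene's transcript spans
  genes <- do.call(rbind, lapply(split(gt, gt$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)))
  lost <- union(setdiff(lt$chrom, genes$chrom), setdiff(genes$chrom, lt$chrom))
  if (length(lost))
    warning("chromosome(s) present in only one input, pairs skipped: ",
            paste(lost, collapse = ", "))
  lnc_gr <- GenomicRanges::GRanges(lt$chrom,
                                   IRanges::IRanges(lt$start, lt$end))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(lnc_gr, gene_gr,
                                      maxgap = max(windows),
                                      ignore.strand = TRUE)
  li <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  d <- ifelse(genes$start[gi] > lt$end[li], genes$start[gi] - lt$end[li],
       ifelse(genes$end[gi] < lt$start[li], genes$end[gi] - lt$start[li], 0))
  keep <- abs(d) <= max(windows)
  li <- li[keep]; gi <- gi[keep]; d <- d[keep]
  w <- windows[vapply(abs(d), function(a) which(a <= windows)[1], 1L)]
  out <- data.frame(lnc_id = lt$transcript_id[li],
                    gene_id = genes$gene_id[gi],
                    distance = d, window = w,
                    window_class = paste0(w / 1000, "k"),
                    stringsAsFactors = FALSE)
  out[order(out$lnc_id, out$gene_id), , drop = FALSE]
}

#' Pearson correlation coefficient
#'
#' Standard product-moment coefficient. Returns `NA` (undefined-flagged)
#' when either vector has zero variance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Pearson r in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' From the exact null distribution of `t = r * sqrt((n - 2) / (1 - r^2))`
#' on `n - 2` degrees of freedom. `|r| = 1` maps to p = 0 (the limit);
#' `NA` r propagates.
#'
#' @param r Pearson coefficient(s).
#' @param n sample size(s), >= 3.
#' @return Two-sided p-value(s).
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 3)) stop("need n >= 3")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) == 1, 0, {
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tstat), df = n - 2)
  })
  p
}

#' Trans target prediction by co-expression
#'
#' Scores every lncRNA x coding-gene pair by Pearson correlation across
#' the shared samples (both groups pooled), attaches two-sided p-values
#' and BH q-values over the full pair family, and retains pairs with
#' `|r| >= r_min`, `p < p_max` and `q < fdr_max`. Pairs with undefined r
#' (zero variance) are scored `NA` and never retained.
#'
#' @param lnc_expr,mrna_expr [ExpressionMatrix()] objects sharing the same
#'   sample set (>= 3 samples).
#' @param r_min minimum absolute Pearson r (default 0.95).
#' @param p_max strict p-value threshold (default 0.01).
#' @param fdr_max strict BH q-value threshold (default 0.01).
#' @param keep_all if `TRUE`, return every scored pair with a logical
#'   `retained` column instead of the retained subset only.
#' @return data.frame of correlation records: `lnc_id`, `gene_id`, `r`,
#'   `n`, `pvalue`, `qvalue` (and `retained` when `keep_all = TRUE`).
#' @export
trans_targets <- function(lnc_expr, mrna_expr, r_min = 0.95,
                          p_max = 0.01, fdr_max = 0.01, keep_all = FALSE) {
  shared <- intersect(sample_ids(lnc_expr), sample_ids(mrna_expr))
  if (length(shared) < 3)
    stop("need >= 3 shared samples, found ", length(shared))
  lv <- t(lnc_expr$values[, shared, drop = FALSE])
  mv <- t(mrna_expr$values[, shared, drop = FALSE])
  n <- length(shared)
  rmat <- suppressWarnings(stats::cor(lv, mv))  # NA for zero-variance rows
  rec <- data.frame(
    lnc_id = rep(rownames(rmat), times = ncol(rmat)),
    gene_id = rep(colnames(rmat), each = nrow(rmat)),
    r = as.vector(rmat), n = n, stringsAsFactors = FALSE)
  rec <- rec[rec$lnc_id != rec$gene_id, , drop = FALSE]
  rec$pvalue <- correlation_pvalue(rec$r, rec$n)
  rec$qvalue <- bh_fdr(rec$pvalue)
  rec$retained <- !is.na(rec$r) & abs(rec$r) >= r_min &
    rec$pvalue < p_max & rec$qvalue < fdr_max
  rec <- rec[order(rec$lnc_id, rec$gene_id), , drop = FALSE]
  row.names(rec) <- NULL
  if (keep_all) rec else {
    out <- rec[rec$retained, setdiff(names(rec), "retained"), drop = FALSE]
    row.names(out) <- NULL
    out
  }
}
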