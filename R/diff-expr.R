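#' Group-level abundance
#'
#' Arithmetic mean of replicate FPKM/TPM over one group's samples, the
#' convention behind published group-level abundance columns.
#'
#' @param expr an [ExpressionMatrix()].
#' @param group group label present in the design.
#' @return Named numeric vector, one mean abundance per feature.
#' @export
group_abundance <- function(expr, group) {
  if (!group %in% expr$design)
    stop("group '", group, "' not present in design")
  cols <- names(expr$design)[expr$design == group]
  rowMeans(expr$values[, cols, drop = FALSE])
}

#' Log2 fold change, catagen over anagen orientation
#'
#' `log2((catagen + pseudocount) / (anagen + pseudocount))`. With the
#' default pseudocount 0, degenerate ratios are carried explicitly rather
#' than dropped: catagen > 0 with anagen 0 gives `+Inf`, the converse
#' `-Inf`, and both zero gives `NaN` (direction undefined).
#'
#' @param catagen,anagen non-negative abundances (vectorized).
#' @param pseudocount non-negative constant added to both before the ratio.
#' @return Numeric vector of log2 ratios (may contain `Inf`/`NaN`).
#' @export
log2_fold_change <- function(catagen, anagen, pseudocount = 0) {
  if (any(catagen < 0, na.rm = TRUE) || any(anagen < 0, na.rm = TRUE))
    stop("abundances must be non-negative")
  log2((catagen + pseudocount) / (anagen + pseudocount))
}

#' Two-group differential-expression test for one feature
#'
#' Documented surrogate engine: Welch's two-sample t-test on
#' `log2(abundance + 1)` across replicates. A feature with zero variance
#' overall (identical in every sample) gets p = 1; a feature constant
#' within each group but different between groups is perfectly separated
#' and gets p = 0.
#'
#' @param expr an [ExpressionMatrix()] whose design has exactly two groups.
#' @param feature feature id.
#' @return Two-sided p-value.
#' @export
de_test <- function(expr, feature) {
  groups <- unique(expr$design)
  if (length(groups) != 2)
    stop("de_test needs exactly two groups, found: ",
         paste(groups, collapse = ", "))
  if (!feature %in% rownames(expr$values))
    stop("feature absent from expression matrix: ", feature)
  x <- log2(expr$values[feature, names(expr$design)[expr$design == groups[1]]] + 1)
  y <- log2(expr$values[feature, names(expr$design)[expr$design == groups[2]]] + 1)
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 samples per group")
  welch_p(x, y)
}

# Welch p with explicit degenerate handling (shared by de_test and de_table)
welch_p <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment with monotonicity enforcement; invariant to the
#' order of the input vector.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential-expression table for all features
#'
#' Computes, per feature: group-level abundances (catagen and anagen
#' arithmetic means), log2 fold change in catagen/anagen orientation, the
#' Welch surrogate p-value, BH q-value and a direction call.
#'
#' @param expr an [ExpressionMatrix()] with groups `"anagen"` and
#'   `"catagen"` (other two-group labels work if `catagen_group` /
#'   `anagen_group` are supplied).
#' @param pseudocount pseudocount for the fold change (default 0).
#' @param catagen_group,anagen_group group labels defining the orientation.
#' @return data.frame with columns `feature_id`, `catagen_abundance`,
#'   `anagen_abundance`, `log2fc`, `pvalue`, `qvalue`, `direction`
#'   (`up`/`down`/`unchanged`/`undefined`; `undefined` when both group
#'   abundances are zero).
#' @export
de_table <- function(expr, pseudocount = 0,
                     catagen_group = "catagen", anagen_group = "anagen") {
  cat_ab <- group_abundance(expr, catagen_group)
  ana_ab <- group_abundance(expr, anagen_group)
  lfc <- log2_fold_change(cat_ab, ana_ab, pseudocount)
  cat_cols <- names(expr$design)[expr$design == catagen_group]
  ana_cols <- names(expr$design)[expr$design == anagen_group]
  logv <- log2(expr$values + 1)
  p <- vapply(rownames(expr$values), function(f)
    welch_p(logv[f, cat_cols], logv[f, ana_cols]), 0)
  direction <- ifelse(cat_ab == 0 & ana_ab == 0, "undefined",
               ifelse(cat_ab > ana_ab, "up",
               ifelse(cat_ab < ana_ab, "down", "unchanged")))
  data.frame(feature_id = rownames(expr$values),
             catagen_abundance = unname(cat_ab),
             anagen_abundance = unname(ana_ab),
             log2fc = unname(lfc), pvalue = unname(p),
             qvalue = bh_fdr(unname(p)), direction = unname(direction),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differentially expressed features
#'
#' A feature is DE iff `pvalue < alpha` (strict). Direction is `up` for
#' positive log2 fold change (catagen relative to anagen), `down` for
#' negative; a DE feature with log2fc exactly 0 keeps direction
#' `unchanged`.
#'
#' @param results a [de_table()] data.frame.
#' @param alpha significance threshold (default 0.05).
#' @return `results` restricted to DE features, with direction recomputed
#'   from the sign of `log2fc`.
#' @export
call_de <- function(results, alpha = 0.05) {
  need <- c("feature_id", "log2fc", "pvalue")
  if (!all(need %in% names(results)))
    stop("results must contain columns: ", paste(need, collapse = ", "))
  de <- results[!is.na(results$pvalue) & results$pvalue < alpha, , drop = FALSE]
  de$direction <- ifelse(is.nan(de$log2fc), "undefined",
                  ifelse(de$log2fc > 0, "up",
                  ifelse(de$log2fc < 0, "down", "unchanged")))
  row.names(de) <- NULL
  de
}

#' Relative expression by the 2^-ddCt method
#'
#' qPCR relative quantification against a reference gene (e.g. beta-actin)
#' and a calibrator sample:
#' `2^-((ct_target_test - ct_ref_test) - (ct_target_calib - ct_ref_calib))`.
#'
#' @param ct_target_test,ct_ref_test,ct_target_calib,ct_ref_calib finite
#'   Ct values.
#' @return Fold change relative to the calibrator.
#' @export
ddct_relative_expression <- function(ct_target_test, ct_ref_test,
                                     ct_target_calib, ct_ref_calib) {
  cts <- c(ct_target_test, ct_ref_test, ct_target_calib, ct_ref_calib)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_calib - ct_ref_calib)
  2^(-ddct)
}
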