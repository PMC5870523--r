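#' Expression matrix with a two-group design
#'
#' Light container for a features x samples abundance table (FPKM for
#' transcripts, TPM for miRNAs) together with the sample -> group design.
#' Values are linear-scale, non-negative abundances; all log transforms
#' happen downstream.
#'
#' @param values numeric matrix, features in rows (unique rownames),
#'   samples in columns (colnames).
#' @param unit abundance unit, `"FPKM"` or `"TPM"`.
#' @param design named character vector mapping every sample (column) to a
#'   group label, e.g. `"anagen"` or `"catagen"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `unit`, `design`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' ExpressionMatrix(m, "FPKM",
#'                  c(s1 = "anagen", s2 = "anagen", s3 = "catagen"))
#' @export
ExpressionMatrix <- function(values, unit = c("FPKM", "TPM"), design) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(colnames(values)) ||
      (nrow(values) > 0 && is.null(rownames(values))))
    stop("`values` must have feature rownames and sample colnames")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyNA(values))
    stop("expression values contain missing entries")
  if (any(values < 0))
    stop("expression values must be non-negative; found ",
         sum(values < 0), " negative entries")
  if (is.null(names(design)))
    stop("`design` must be a named character vector (sample -> group)")
  missing_design <- setdiff(colnames(values), names(design))
  extra_design <- setdiff(names(design), colnames(values))
  if (length(missing_design) || length(extra_design))
    stop("design/sample mismatch; samples without a group: [",
         paste(missing_design, collapse = ", "),
         "]; design entries without a sample: [",
         paste(extra_design, collapse = ", "), "]")
  structure(
    list(values = values, unit = unit,
         design = design[colnames(values)]),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  tab <- table(x$design)
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Feature ids of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' Sample ids of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an ExpressionMatrix by features
#' @param x an `ExpressionMatrix`.
#' @param features character vector of feature ids to keep (order kept).
#' @return An `ExpressionMatrix` restricted to `features`.
#' @export
subset_features <- function(x, features) {
  missing <- setdiff(features, rownames(x$values))
  if (length(missing))
    stop("features absent from expression matrix: ",
         paste(missing, collapse = ", "))
  ExpressionMatrix(x$values[features, , drop = FALSE], x$unit, x$design)
}

#' Read a sample -> group design table
#'
#' TSV with columns `sample_id` and `group`.
#'
#' @param path file path.
#' @return Named character vector mapping sample ids to group labels.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df)))
    stop("design table must have columns sample_id, group; found: ",
         paste(names(df), collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in design table")
  stats::setNames(as.character(df$group), df$sample_id)
}

#' Read an expression table (TSV)
#'
#' First column `feature_id`, remaining columns one per sample, header row
#' of sample ids. Values must be non-negative and complete.
#'
#' @param path file path.
#' @param unit `"FPKM"` or `"TPM"`.
#' @param design named character vector (see [read_design()]); every design
#'   sample must be present as a column and vice versa.
#' @return An [ExpressionMatrix()].
#' @export
read_expression_table <- function(path, unit = c("FPKM", "TPM"), design) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "feature_id")
    stop("expression table must start with a feature_id column, found: ",
         names(df)[1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(vals) == 0)
    vals <- matrix(numeric(0), 0, ncol(df) - 1,
                   dimnames = list(character(0), names(df)[-1]))
  if (!is.numeric(vals))
    stop("non-numeric expression values in ", path)
  rownames(vals) <- df$feature_id
  ExpressionMatrix(vals, unit, design)
}

#' Write an expression table (TSV)
#'
#' Inverse of [read_expression_table()]; values are written with enough
#' digits (R's default 15 significant) to round-trip typical text-precision
#' values bit-identically.
#'
#' @param x an `ExpressionMatrix`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(x, path) {
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a design table (TSV)
#' @param design named character vector (sample -> group).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_design <- function(design, path) {
  utils::write.table(
    data.frame(sample_id = names(design), group = unname(design)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
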