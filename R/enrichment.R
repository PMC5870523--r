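#' Over-representation analysis of gene sets
#'
#' Generic GO/KEGG-style enrichment of a study gene list against a
#' population, per term, by the hypergeometric upper tail
#' `P(X >= k)` with `k` study hits, `K` term genes in the population,
#' `n` study genes and `N` population genes. Terms are first restricted to
#' the population; terms with no study hit are excluded. q-values are BH
#' over all tested terms and results are sorted by q then p. The rich
#' factor is `k / K`, the fraction of a term's genes hit by the study set.
#'
#' @param study_genes character vector, must be a subset of
#'   `population_genes`.
#' @param population_genes character vector (the expressed background).
#' @param term_to_genes named list: term id -> character vector of genes,
#'   or a data.frame with columns `term` and `gene`.
#' @param term_names optional named character vector of term descriptions.
#' @return data.frame with columns `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `rich_factor`, `pvalue`, `qvalue`.
#' @export
enrich <- function(study_genes, population_genes, term_to_genes,
                   term_names = NULL) {
  study_genes <- unique(study_genes)
  population_genes <- unique(population_genes)
  bad <- setdiff(study_genes, population_genes)
  if (length(bad))
    stop("study gene(s) absent from population: ",
         paste(bad, collapse = ", "))
  if (is.data.frame(term_to_genes)) {
    if (!all(c("term", "gene") %in% names(term_to_genes)))
      stop("term table must have columns term, gene")
    term_to_genes <- split(term_to_genes$gene, term_to_genes$term)
  }
  N <- length(population_genes)
  n <- length(study_genes)
  rows <- lapply(names(term_to_genes), function(term) {
    genes <- intersect(unique(term_to_genes[[term]]), population_genes)
    K <- length(genes)
    k <- length(intersect(genes, study_genes))
    if (k == 0) return(NULL)
    data.frame(term_id = term,
               term_name = if (!is.null(term_names) &&
                               term %in% names(term_names))
                 unname(term_names[term]) else term,
               k = k, K = K, n = n, N = N, rich_factor = k / K,
               pvalue = stats::phyper(k - 1, K, N - K, n,
                                      lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), rich_factor = numeric(),
                      pvalue = numeric(), qvalue = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$qvalue <- bh_fdr(out$pvalue)
  out <- out[order(out$qvalue, out$pvalue, out$term_id), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Read a gene-set table (term -> gene TSV)
#'
#' @param path TSV with columns `term` and `gene` (optionally
#'   `term_name`).
#' @return Named list term -> gene character vector, with a `term_names`
#'   attribute when descriptions are present.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term", "gene") %in% names(df)))
    stop("gene-set table must have columns term, gene")
  sets <- split(df$gene, df$term)
  if ("term_name" %in% names(df)) {
    nm <- df[!duplicated(df$term), c("term", "term_name")]
    attr(sets, "term_names") <- stats::setNames(nm$term_name, nm$term)
  }
  sets
}
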