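#' Export a ceRNA triad network
#'
#' Writes the lncRNA-miRNA-mRNA network implied by a set of triads, one
#' lncRNA-miRNA and one miRNA-mRNA edge per triad, deduplicated.
#'
#' * `SIF`: tab-separated `source  relationship  target` lines
#'   (`sponges` for lncRNA->miRNA, `represses` for miRNA->mRNA).
#' * `GraphML` (via igraph): nodes carry a `type` attribute
#'   (`lncRNA`/`miRNA`/`mRNA`), the conventional `shape` semantics
#'   (triangle = lncRNA, circle = miRNA, square = mRNA) and a `direction`
#'   attribute derived from the triad patterns (`up`/`down`;
#'   `conflicting` if a node is assigned both, `unknown` for nodes only in
#'   discordant triads); edges carry a `relationship` attribute.
#'
#' An empty triad set yields an empty but well-formed file.
#'
#' @param triads data.frame from [build_triads()].
#' @param format `"SIF"` or `"GraphML"`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(triads, format = c("SIF", "GraphML"), path) {
  format <- match.arg(format)
  edges <- network_edges(triads)
  if (format == "SIF") {
    writeLines(sprintf("%s\t%s\t%s", edges$from, edges$relationship,
                       edges$to), path)
    return(invisible(path))
  }
  nodes <- network_nodes(triads)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "relationship")], directed = TRUE,
    vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# deduplicated edge table: lnc -> miRNA ("sponges"), miRNA -> mRNA
# ("represses")
network_edges <- function(triads) {
  if (!nrow(triads))
    return(data.frame(from = character(), to = character(),
                      relationship = character(), stringsAsFactors = FALSE))
  e <- rbind(
    data.frame(from = triads$lnc_id, to = triads$mirna_id,
               relationship = "sponges", stringsAsFactors = FALSE),
    data.frame(from = triads$mirna_id, to = triads$mrna_id,
               relationship = "represses", stringsAsFactors = FALSE))
  e <- unique(e)
  e[order(e$relationship, e$from, e$to), , drop = FALSE]
}

# node table with type/shape/direction attributes
network_nodes <- function(triads) {
  if (!nrow(triads))
    return(data.frame(name = character(), type = character(),
                      shape = character(), direction = character(),
                      stringsAsFactors = FALSE))
  pat_dir <- function(pattern, slot) {
    # slot 1 = lnc, 2 = miRNA, 3 = mRNA
    vapply(pattern, function(p) switch(
      p,
      `up-down-up` = c("up", "down", "up")[slot],
      `down-up-down` = c("down", "up", "down")[slot],
      "unknown"), "")
  }
  nd <- rbind(
    data.frame(name = triads$lnc_id, type = "lncRNA", shape = "triangle",
               direction = pat_dir(triads$pattern, 1),
               stringsAsFactors = FALSE),
    data.frame(name = triads$mirna_id, type = "miRNA", shape = "circle",
               direction = pat_dir(triads$pattern, 2),
               stringsAsFactors = FALSE),
    data.frame(name = triads$mrna_id, type = "mRNA", shape = "square",
               direction = pat_dir(triads$pattern, 3),
               stringsAsFactors = FALSE))
  rows <- lapply(split(nd, nd$name), function(d) {
    dirs <- setdiff(unique(d$direction), "unknown")
    d$direction <- if (length(dirs) == 1) dirs else
      if (length(dirs) > 1) "conflicting" else "unknown"
    d[1, , drop = FALSE]
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$name), , drop = FALSE]
}
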