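#' Transcript model
#'
#' A transcript's genomic structure: chromosome, strand and exon set in
#' 1-based inclusive coordinates, plus biotype bookkeeping used by the
#' novel-lncRNA filter.
#'
#' @param transcript_id,gene_id character scalars.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column numeric matrix (start, end), 1-based inclusive;
#'   exons must be non-overlapping. They are stored sorted by genomic start.
#' @param biotype one of `"coding"`, `"known_lncRNA"`, `"unknown"`.
#' @return An object of class `TranscriptModel`.
#' @export
TranscriptModel <- function(transcript_id, gene_id, chrom, strand,
                            exons, biotype = "unknown") {
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for ", transcript_id)
  if (!biotype %in% c("coding", "known_lncRNA", "unknown"))
    stop("invalid biotype '", biotype, "' for ", transcript_id)
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0)
    stop("transcript ", transcript_id, " has no exons")
  if (any(exons[, "start"] > exons[, "end"]))
    stop("exon start > end in transcript ", transcript_id)
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons[-1, "start"] <= exons[-nrow(exons), "end"]))
    stop("overlapping exons in transcript ", transcript_id)
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         chrom = chrom, strand = strand, exons = exons, biotype = biotype),
    class = "TranscriptModel"
  )
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s) %s:%d-%d(%s) %d exon(s), %d bp, %s\n",
              x$transcript_id, x$gene_id, x$chrom,
              min(x$exons[, "start"]), max(x$exons[, "end"]), x$strand,
              nrow(x$exons), transcript_length(x), x$biotype))
  invisible(x)
}

#' Spliced length of a transcript (sum of exon lengths)
#' @param x a `TranscriptModel`.
#' @return Integer spliced length in bp.
#' @export
transcript_length <- function(x) {
  sum(x$exons[, "end"] - x$exons[, "start"] + 1)
}

#' Summarise a list of transcript models as a data frame
#'
#' @param models list of `TranscriptModel`.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `start`, `end` (locus span),
#'   `n_exons`, `length` (spliced), `biotype`.
#' @export
transcript_table <- function(models) {
  data.frame(
    transcript_id = vapply(models, `[[`, "", "transcript_id"),
    gene_id = vapply(models, `[[`, "", "gene_id"),
    chrom = vapply(models, `[[`, "", "chrom"),
    strand = vapply(models, `[[`, "", "strand"),
    start = vapply(models, function(m) min(m$exons[, "start"]), 0),
    end = vapply(models, function(m) max(m$exons[, "end"]), 0),
    n_exons = vapply(models, function(m) nrow(m$exons), 0L),
    length = vapply(models, transcript_length, 0),
    biotype = vapply(models, `[[`, "", "biotype"),
    stringsAsFactors = FALSE
  )
}

# Cheap structural pre-validation so parse failures name the line number;
# the actual parsing is delegated to rtracklayer.
validate_gtf_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9)
      stop("malformed GTF line ", i, " in ", path,
           ": expected 9 tab-separated fields, found ", length(fields))
    if (is.na(suppressWarnings(as.integer(fields[4]))) ||
        is.na(suppressWarnings(as.integer(fields[5]))))
      stop("malformed GTF line ", i, " in ", path,
           ": non-numeric start/end")
  }
  invisible(lines)
}

#' Read transcript models from a GTF file
#'
#' Parses a GTF2.2 file (via rtracklayer) into a list of
#' [TranscriptModel()] records, one per `transcript_id`, with exons grouped
#' and sorted and coordinates kept 1-based inclusive. Biotypes are assigned
#' from the supplied id sets; ids in neither set are `"unknown"`.
#'
#' Transcripts declared by a `transcript` feature row but having no exon
#' rows are skipped with a warning. A `transcript_id` declared by more than
#' one `transcript` row is an error (ambiguous annotation fails loudly
#' rather than last-wins).
#'
#' @param path GTF file path.
#' @param coding_ids character vector of transcript ids known to be coding.
#' @param known_lnc_ids character vector of transcript ids of known lncRNAs.
#' @return List of `TranscriptModel`, named by transcript id.
#' @export
read_gtf <- function(path, coding_ids = character(),
                     known_lnc_ids = character()) {
  if (!file.exists(path)) stop("no such GTF file: ", path)
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!all(c("type", "transcript_id", "gene_id") %in% names(meta)))
    stop("GTF at ", path, " lacks transcript_id/gene_id attributes")
  declared <- as.character(meta$transcript_id[meta$type == "transcript"])
  if (anyDuplicated(declared))
    stop("duplicate transcript_id in GTF: ",
         paste(unique(declared[duplicated(declared)]), collapse = ", "))
  ex <- gr[meta$type == "exon"]
  ex_tx <- as.character(S4Vectors::mcols(ex)$transcript_id)
  orphan <- setdiff(declared, unique(ex_tx))
  if (length(orphan))
    warning("skipping transcript(s) with zero exon rows: ",
            paste(orphan, collapse = ", "))
  tx_ids <- unique(ex_tx)
  idx <- split(seq_along(ex), ex_tx)[tx_ids]
  models <- lapply(tx_ids, function(tid) {
    rows <- ex[idx[[tid]]]
    chrom <- unique(as.character(GenomicRanges::seqnames(rows)))
    strand <- unique(as.character(GenomicRanges::strand(rows)))
    if (length(chrom) != 1 || length(strand) != 1)
      stop("transcript ", tid, " spans multiple chromosomes or strands")
    biotype <- if (tid %in% coding_ids) "coding"
      else if (tid %in% known_lnc_ids) "known_lncRNA"
      else "unknown"
    TranscriptModel(
      tid, as.character(S4Vectors::mcols(rows)$gene_id[1]), chrom, strand,
      cbind(GenomicRanges::start(rows), GenomicRanges::end(rows)), biotype)
  })
  names(models) <- tx_ids
  models
}

#' Write transcript models to a GTF file
#'
#' Emits one `transcript` row and one `exon` row per exon, 1-based
#' inclusive, with `gene_id`/`transcript_id` attributes. Output is
#' deterministic (fixed field formatting), so identical inputs produce
#' byte-identical files.
#'
#' @param models list of `TranscriptModel`.
#' @param path output file path.
#' @param source source field to write (column 2).
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(models, path, source = "cernet") {
  lines <- unlist(lapply(models, function(m) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     m$gene_id, m$transcript_id)
    c(sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              m$chrom, source, min(m$exons[, "start"]),
              max(m$exons[, "end"]), m$strand, attrs),
      sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
              m$chrom, source, m$exons[, "start"], m$exons[, "end"],
              m$strand, attrs))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
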