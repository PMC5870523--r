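#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and U is normalized to T on load, so all
#' downstream matching (including miRNA seed matching) happens in a single
#' DNA alphabet. Only A/C/G/T/U/N are accepted.
#'
#' @param path FASTA file path.
#' @return Named character vector of DNA-alphabet sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence(s) with characters outside {A,C,G,T,U,N}: ",
         paste(names(seqs)[bad], collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence(s): ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# reverse complement in the DNA alphabet (character in, character out)
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE))
}
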