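#' Read a protein FASTA file into a sequence-record table
#'
#' Wraps \pkg{Biostrings} FASTA parsing and applies the package conventions
#' for noisy transcriptome data: trailing \code{*} stop characters are
#' stripped, residues outside the 20-letter alphabet become \code{X} (with a
#' warning), records with empty sequences are skipped with a warning, and an
#' empty file yields an empty table with a warning.  The record id is the
#' header token before the first whitespace; the remainder is kept as the
#' description.
#'
#' @param path FASTA file.
#' @param library_id optional library identifier attached to every record.
#' @return data.frame with columns \code{id}, \code{description},
#'   \code{sequence}, \code{library_id}, \code{scaffold_id} (NA unless set
#'   later), in file order.
#' @export
read_fasta <- function(path, library_id = NA_character_) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  empty <- data.frame(id = character(), description = character(),
                      sequence = character(), library_id = character(),
                      scaffold_id = character(), stringsAsFactors = FALSE)
  if (file.size(path) == 0) {
    warnf("empty FASTA file: %s", path)
    return(empty)
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) {
    warnf("no records in FASTA file: %s", path)
    return(empty)
  }
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(ss))
  seqs <- sub("\\*+$", "", seqs)
  keep <- nchar(seqs) > 0
  if (any(!keep)) {
    warnf("skipping %d record(s) with empty sequence", sum(!keep))
    ids <- ids[keep]; desc <- desc[keep]; seqs <- seqs[keep]
  }
  nonstd <- grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), seqs)
  if (any(nonstd)) {
    warnf("mapping non-alphabet residues to X in %d record(s)", sum(nonstd))
    seqs <- gsub(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), "X", seqs)
  }
  data.frame(id = ids, description = desc, sequence = seqs,
             library_id = library_id, scaffold_id = NA_character_,
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with \code{id} and \code{sequence} columns (the
#'   shape produced by [read_fasta()]), or a named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  ss <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
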