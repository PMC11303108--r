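#' Read named sequences from FASTA
#'
#' Sequences are upper-cased on read and restricted to the `ACGTN`
#' alphabet; `N` bases are retained but never match any motif word during
#' scanning. Record names are truncated at the first whitespace.
#'
#' @param path Path to a plain (uncompressed) FASTA file.
#' @return A named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(seqs))) {
    stop("empty FASTA record: ", names(seqs)[!nzchar(seqs)][1L])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ch <- regmatches(seqs[bad][1L], regexpr("[^ACGTN]", seqs[bad][1L]))
    stop("invalid character '", ch, "' in record ", names(seqs)[bad][1L],
         " (alphabet is ACGTN, case-insensitive)")
  }
  seqs
}

#' Write named sequences as FASTA
#'
#' Inverse of [read_fasta()]; wraps lines at 70 bases.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  ss <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
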