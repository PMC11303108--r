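## AP-1/TRE motif words. The TRE consensus TGA(C/G)TCA expands to the two
## 7-mers TGACTCA and TGAGTCA, which are reverse complements of each other:
## a genomic TRE is therefore reported once, with strand "+" when read as
## TGACTCA and "-" when the forward strand reads TGAGTCA. The half site is
## the invariant 4-mer TGAC (forward) / GTCA (the reverse-strand reading).
TRE_PLUS <- "TGACTCA"
TRE_MINUS <- "TGAGTCA"
HALF_PLUS <- "TGAC"
HALF_MINUS <- "GTCA"

motif_hits_frame <- function(position = integer(), strand = character(),
                             kind = character(), matched_text = character(),
                             embedded = NULL) {
  n <- length(position)
  out <- data.frame(position = as.integer(position),
                    strand = rep_len(as.character(strand), n),
                    kind = rep_len(as.character(kind), n),
                    matched_text = rep_len(as.character(matched_text), n),
                    stringsAsFactors = FALSE)
  if (!is.null(embedded)) out$embedded <- as.logical(embedded)
  out[order(out$position, out$strand), , drop = FALSE]
}

match_word <- function(sequence, word) {
  subj <- Biostrings::DNAString(sequence)
  m <- Biostrings::matchPattern(word, subj, fixed = TRUE)  # N never matches
  Biostrings::start(m) - 1L  # 0-based
}

#' Scan a sequence for full TRE (AP-1) sites
#'
#' Reports every occurrence of the TRE consensus TGA(C/G)TCA: positions of
#' `TGACTCA` with strand `+` and of `TGAGTCA` (its reverse complement, i.e.
#' a minus-strand TRE) with strand `-`. Each genomic site is reported once.
#' `N` bases never match.
#'
#' @param sequence A single upper-case `ACGTN` string.
#' @return A `data.frame` of hits with columns `position` (0-based),
#'   `strand`, `kind` (`"full_TRE"`), `matched_text`.
#' @export
#' @examples
#' scan_tre("TGACTCA")   # one hit at position 0
#' scan_tre("TTACTCA")   # the TGAC -> TTAC mutation: no hits
scan_tre <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  p <- match_word(sequence, TRE_PLUS)
  m <- match_word(sequence, TRE_MINUS)
  motif_hits_frame(
    position = c(p, m),
    strand = c(rep("+", length(p)), rep("-", length(m))),
    kind = "full_TRE",
    matched_text = c(rep(TRE_PLUS, length(p)), rep(TRE_MINUS, length(m)))
  )
}

#' Scan a sequence for AP-1 half sites
#'
#' Reports every occurrence of the invariant half-site 4-mer: `TGAC` with
#' strand `+` and `GTCA` (its reverse-strand reading) with strand `-`.
#' Half sites lying entirely inside a full TRE occurrence are annotated
#' `embedded = TRUE`.
#'
#' @inheritParams scan_tre
#' @return A `data.frame` of hits with columns `position`, `strand`, `kind`
#'   (`"half_site"`), `matched_text`, `embedded`.
#' @export
scan_half_sites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  p <- match_word(sequence, HALF_PLUS)
  m <- match_word(sequence, HALF_MINUS)
  pos <- c(p, m)
  full <- scan_tre(sequence)
  embedded <- vapply(pos, function(q) {
    any(q >= full$position & q + 4L <= full$position + 7L)
  }, logical(1))
  motif_hits_frame(
    position = pos,
    strand = c(rep("+", length(p)), rep("-", length(m))),
    kind = "half_site",
    matched_text = c(rep(HALF_PLUS, length(p)), rep(HALF_MINUS, length(m))),
    embedded = embedded
  )
}

#' Mutate a motif site in place
#'
#' Replaces the matched text of one motif hit with `replacement_word`
#' (e.g. the TGAC to TTAC point mutation that abolishes AP-1 binding).
#' The hit must still match the sequence at its recorded position.
#'
#' @param sequence The sequence the hit was found in.
#' @param hit One row of a hit frame from [scan_tre()] or
#'   [scan_half_sites()] (a list or one-row data.frame with `position` and
#'   `matched_text`).
#' @param replacement_word Replacement string (any length).
#' @return The mutated sequence.
#' @export
#' @examples
#' h <- scan_half_sites("TGACTCA")[1, ]
#' mutate_site("TGACTCA", h, "TTAC")  # "TTACTCA"
mutate_site <- function(sequence, hit, replacement_word) {
  pos <- as.integer(hit$position)
  word <- as.character(hit$matched_text)
  found <- substr(sequence, pos + 1L, pos + nchar(word))
  if (!identical(found, word)) {
    stop("hit/sequence mismatch at position ", pos, ": expected '", word,
         "', found '", found, "'")
  }
  paste0(substr(sequence, 1L, pos),
         replacement_word,
         substr(sequence, pos + nchar(word) + 1L, nchar(sequence)))
}
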