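# Small sequence utilities shared across modules. All coordinates in this
# package are 0-based half-open unless a reader/writer says otherwise.

#' Reverse complement of a nucleotide string
#'
#' Plain-character implementation handling A/C/G/T/N (case preserved).
#'
#' @param x single nucleotide string
#' @return reverse-complemented string
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(x)
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Translate a coding sequence
#'
#' Standard-code translation starting at `frame_offset`, stopping at (and
#' excluding) the first stop codon; a trailing partial codon is dropped.
#' Codons containing N (or any non-ACGT character) translate to `X` so that
#' positional alignment with the nucleotide sequence is preserved.
#'
#' @param cds nucleotide string (coding strand, 5'->3')
#' @param frame_offset 0, 1 or 2: number of leading bases to skip
#' @return amino-acid string (possibly empty)
#' @export
translate_cds <- function(cds, frame_offset = 0L) {
  stopifnot(is.character(cds), length(cds) == 1L)
  frame_offset <- as.integer(frame_offset)
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  s <- substr(cds, frame_offset + 1L, nchar(cds))
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

# phred+33 decoding of a SAM QUAL string -> integer vector
phred_from_qual <- function(qual) {
  if (is.na(qual) || qual == "*") return(integer(0))
  utf8ToInt(qual) - 33L
}

# stable deterministic string sort (C locale) so reports do not depend on
# the session collation
c_sort <- function(x) x[order(x, method = "radix")]

# drop-log record used throughout the pipeline
drop_record <- function(variant_id, stage, reason) {
  list(variant = variant_id, stage = stage, reason = reason)
}
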