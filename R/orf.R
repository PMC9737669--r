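#' @include AllClasses.R
NULL

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame of an oriented transcript sequence
#'
#' Scans the three forward frames of the given (already strand-oriented,
#' 5'->3') sequence for ATG..stop open reading frames and returns the
#' longest. The reported length is in nucleotides and includes the stop
#' codon, so the minimal ORF `ATGTAA` has length 6. An ORF requires an
#' in-frame stop; a start codon running off the 3' end does not count.
#'
#' @param sequence a character scalar, `DNAString`, or anything coercible by
#'   `as.character`; alphabet `A/C/G/T/N` (N never matches start or stop).
#' @return list with `length` (nt, 0 if no ORF), `frame` (1-3), `start` and
#'   `end` (1-based nucleotide positions, `end` is the stop codon's last
#'   base); `frame`/`start`/`end` are `NA` when no ORF exists.
#' @examples
#' longestOrf("ATGTAA")$length     # 6
#' longestOrf("CCCCCC")$length     # 0
#' @export
longestOrf <- function(sequence) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  none <- list(length = 0L, frame = NA_integer_, start = NA_integer_,
               end = NA_integer_)
  if (n < 6L) return(none)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  best <- none
  for (f in 0:2) {
    first <- seq.int(1L + f, n - 2L, by = 3L)
    if (length(first) < 2L) next
    codons <- paste0(chars[first], chars[first + 1L], chars[first + 2L])
    startIdx <- which(codons == "ATG")
    stopIdx <- which(codons %in% .STOP_CODONS)
    if (!length(startIdx) || !length(stopIdx)) next
    # first stop strictly after each start codon
    nxt <- findInterval(startIdx, stopIdx) + 1L
    ok <- nxt <= length(stopIdx)
    if (!any(ok)) next
    len <- (stopIdx[nxt[ok]] - startIdx[ok] + 1L) * 3L
    i <- which.max(len)
    if (len[i] > best$length) {
      sIdx <- startIdx[ok][i]
      eIdx <- stopIdx[nxt[ok][i]]
      best <- list(length = len[i], frame = f + 1L,
                   start = f + 3L * (sIdx - 1L) + 1L,
                   end = f + 3L * eIdx)
    }
  }
  best
}

#' Coding-potential score and call for transcript sequences
#'
#' A transparent ORF-based stand-in for coding-potential classifiers: the
#' score combines ORF length (in units of 300 nt) and ORF coverage of the
#' transcript, and a transcript is called coding when its longest ORF is at
#' least `orfCoding` nt, or at least `orfPartial` nt while covering at least
#' `coverageMin` of the transcript. Extending an ORF never lowers the score.
#' Precomputed calls from an external classifier can be supplied to
#' [filterCascade()] instead via its `coding` argument.
#'
#' @param sequences a named character vector or `DNAStringSet` of oriented
#'   transcript sequences.
#' @param orfCoding ORF length (nt) that alone implies coding; default 300
#'   (inclusive).
#' @param orfPartial ORF length that implies coding when coverage is also
#'   met; default 200 (inclusive).
#' @param coverageMin ORF coverage threshold used with `orfPartial`;
#'   default 0.5 (inclusive).
#' @param w1,w2 score weights for ORF length and coverage; default 1 each.
#' @return a [S4Vectors::DataFrame] with columns `transcript_id`,
#'   `longest_orf_nt`, `orf_coverage`, `score`, `is_coding`.
#' @export
codingPotential <- function(sequences, orfCoding = 300L, orfPartial = 200L,
                            coverageMin = 0.5, w1 = 1, w2 = 1) {
  seqs <- setNames(as.character(sequences), names(sequences))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  orf <- unname(vapply(seqs, function(x) longestOrf(x)$length, integer(1),
                       USE.NAMES = FALSE))
  len <- nchar(seqs)
  cov <- unname(ifelse(len > 0L, orf / len, 0))
  score <- w1 * orf / 300 + w2 * cov
  coding <- orf >= orfCoding | (orf >= orfPartial & cov >= coverageMin)
  DataFrame(transcript_id = ids, longest_orf_nt = as.integer(orf),
            orf_coverage = cov, score = score, is_coding = coding,
            row.names = ids)
}
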