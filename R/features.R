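# ORF/UTR annotation and length summaries.

#' Annotate the ORF and UTRs of a transcript
#'
#' The ORF runs from the conserved start codon through the first in-frame
#' stop codon, stop codon included. UTR lengths are measured on the
#' poly(A)-trimmed sequence: \code{utr5_len = conserved_start_pos - 1} and
#' \code{utr3_len = trimmedLen - orf_end}, so that
#' \code{utr5_len + orf_len + utr3_len == trimmedLen}.
#'
#' @param seq DNA sequence string.
#' @param conservedStartPos 1-based position of the accepted ATG.
#' @param trimmedLen length of the sequence after poly(A) removal
#'   (defaults to the full length when no tail is present).
#' @return list with \code{orf_start}, \code{orf_end}, \code{orf_len},
#'   \code{utr5_len}, \code{utr3_len}. When no in-frame stop codon lies
#'   within the trimmed sequence, \code{orf_end} is NA (the
#'   \code{missing_stop} state, propagated to classification rather than
#'   raised as an error).
#' @export
annotateOrf <- function(seq, conservedStartPos, trimmedLen = nchar(seq)) {
  if (substr(seq, conservedStartPos, conservedStartPos + 2L) != "ATG")
    stop("no ATG at the given conserved start position ", conservedStartPos)
  stopPos <- firstInFrameStop(seq, conservedStartPos, trimmedLen)
  if (is.na(stopPos))
    return(list(orf_start = conservedStartPos, orf_end = NA_integer_,
                orf_len = NA_integer_,
                utr5_len = conservedStartPos - 1L, utr3_len = NA_integer_))
  orfEnd <- stopPos + 2L
  list(orf_start = conservedStartPos,
       orf_end = orfEnd,
       orf_len = orfEnd - conservedStartPos + 1L,
       utr5_len = conservedStartPos - 1L,
       utr3_len = trimmedLen - orfEnd)
}

#' Summarize ORF and UTR lengths
#'
#' Produces the per-species resource summary (counts, mean/min/max of
#' sequence, ORF and 3'UTR lengths) and length histograms with left-closed
#' bins \code{[k*w, (k+1)*w)}. Means are reported to the nearest bp.
#'
#' @param calls classification data.frame from
#'   \code{\link{classifyTranscripts}}; rows without ORF coordinates are
#'   ignored.
#' @param binWidthOrf histogram bin width for ORF lengths (default 300 bp).
#' @param binWidthUtr histogram bin width for 3'UTR lengths (default 100
#'   bp).
#' @return list with \code{n}, \code{mean_seq_len}, \code{mean_orf_len},
#'   \code{mean_utr3_len}, a \code{range} data.frame (min/max per field)
#'   and two histogram data.frames (\code{orf_hist}, \code{utr3_hist})
#'   with columns \code{bin_start}, \code{bin_end}, \code{count}.
#' @export
summarizeLengths <- function(calls, binWidthOrf = 300L, binWidthUtr = 100L) {
  ann <- calls[!is.na(calls$orf_len), , drop = FALSE]
  if (nrow(ann) == 0L) stop("no annotated transcripts to summarize")
  seqLen <- ann$trimmed_len
  list(
    n = nrow(ann),
    mean_seq_len = roundHalfUp(mean(seqLen)),
    mean_orf_len = roundHalfUp(mean(ann$orf_len)),
    mean_utr3_len = roundHalfUp(mean(ann$utr3_len)),
    range = data.frame(
      field = c("seq_len", "orf_len", "utr3_len"),
      min = c(min(seqLen), min(ann$orf_len), min(ann$utr3_len)),
      max = c(max(seqLen), max(ann$orf_len), max(ann$utr3_len)),
      stringsAsFactors = FALSE),
    orf_hist = lengthHistogram(ann$orf_len, binWidthOrf),
    utr3_hist = lengthHistogram(ann$utr3_len, binWidthUtr)
  )
}

# Left-closed bins [k*w, (k+1)*w); empty bins inside the occupied range
# are kept so the histogram plots as a proper distribution.
lengthHistogram <- function(x, w) {
  k <- x %/% w
  kk <- seq.int(min(k), max(k))
  counts <- tabulate(k - min(k) + 1L, nbins = length(kk))
  data.frame(bin_start = kk * w, bin_end = (kk + 1L) * w,
             count = counts)
}
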