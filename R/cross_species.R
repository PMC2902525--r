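# Two-species ortholog comparison: pair transcripts sharing a gene
# identity, align ORF and 3'UTR regions globally, and summarize percent
# identities.

#' Pair transcripts between two species by shared gene identity
#'
#' One pair per subject id present in both species' classifications. When
#' a species has several transcripts for one subject, the lowest-E-value
#' representative is chosen (ties broken by transcript id) and the event
#' recorded in the \code{multiMapped} attribute.
#'
#' @param callsA,callsB classification data.frames for species A and B;
#'   rows must carry \code{best_hit_subject} and \code{evalue}.
#' @return data.frame with columns \code{gene_id}, \code{id_A},
#'   \code{id_B}; attribute \code{multiMapped} lists subjects that had
#'   several candidate transcripts in a species.
#' @export
pairByIdentity <- function(callsA, callsB) {
  repOf <- function(calls) {
    cc <- calls[!is.na(calls$best_hit_subject), , drop = FALSE]
    cc <- cc[order(cc$best_hit_subject, cc$evalue, cc$transcript_id,
                   method = "radix"), , drop = FALSE]
    multi <- unique(cc$best_hit_subject[duplicated(cc$best_hit_subject)])
    list(rep = cc[!duplicated(cc$best_hit_subject), , drop = FALSE],
         multi = multi)
  }
  a <- repOf(callsA); b <- repOf(callsB)
  shared <- sort(intersect(a$rep$best_hit_subject, b$rep$best_hit_subject))
  out <- data.frame(
    gene_id = shared,
    id_A = a$rep$transcript_id[match(shared, a$rep$best_hit_subject)],
    id_B = b$rep$transcript_id[match(shared, b$rep$best_hit_subject)],
    stringsAsFactors = FALSE)
  attr(out, "multiMapped") <- sort(unique(c(a$multi, b$multi)))
  out
}

#' Global percent identity between two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, linear
#' gap penalty -2 and free terminal gaps (ends-free alignment). Identity
#' is matches divided by alignment columns, excluding columns that are
#' terminal-gap in either sequence, times 100, rounded half-up to an
#' integer (97.5 reports as 98).
#'
#' @param x,y DNA sequence strings (nonempty).
#' @param round round to the nearest whole number (default TRUE).
#' @return integer percent identity in [0, 100].
#' @export
globalIdentity <- function(x, y, round = TRUE) {
  if (!nzchar(x) || !nzchar(y)) stop("globalIdentity needs nonempty sequences")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(x, y, type = "overlap",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  # overlap alignments clip terminal-gap columns from the aligned strings
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  if (length(pa) == 0L) return(if (round) 0L else 0)
  pct <- 100 * sum(pa == sa & pa != "-") / length(pa)
  if (round) as.integer(roundHalfUp(pct)) else pct
}

#' ORF and 3'UTR identities for ortholog pairs
#'
#' Extracts each pair member's ORF and 3'UTR from its classification
#' coordinates and computes \code{\link{globalIdentity}} per region.
#' Pairs with an empty region in either member are skipped for that
#' region with a warning.
#'
#' @param pairs data.frame from \code{\link{pairByIdentity}}.
#' @param tsA,tsB \linkS4class{TranscriptSet}s for the two species.
#' @param callsA,callsB their classification data.frames.
#' @return the \code{pairs} data.frame with added integer columns
#'   \code{orf_identity} and \code{utr3_identity} (NA when skipped).
#' @export
orthologIdentities <- function(pairs, tsA, callsA, tsB, callsB) {
  seqA <- seqStrings(tsA); seqB <- seqStrings(tsB)
  region <- function(calls, seqs, id, what) {
    r <- calls[calls$transcript_id == id, , drop = FALSE]
    if (nrow(r) != 1L || is.na(r$orf_len)) return("")
    if (what == "orf") {
      substr(seqs[[id]], r$orf_start, r$orf_end)
    } else {
      if (r$utr3_len <= 0L) "" else
        substr(seqs[[id]], r$orf_end + 1L, r$trimmed_len)
    }
  }
  pairs$orf_identity <- rep(NA_integer_, nrow(pairs))
  pairs$utr3_identity <- rep(NA_integer_, nrow(pairs))
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    for (reg in c("orf", "utr3")) {
      sx <- region(callsA, seqA, pairs$id_A[i], reg)
      sy <- region(callsB, seqB, pairs$id_B[i], reg)
      if (!nzchar(sx) || !nzchar(sy)) { skipped <- skipped + 1L; next }
      pairs[[paste0(if (reg == "orf") "orf" else "utr3", "_identity")]][i] <-
        globalIdentity(sx, sy)
    }
  }
  if (skipped > 0L)
    warning(skipped, " empty region comparison(s) skipped")
  pairs
}

#' Histogram of ortholog percent identities
#'
#' Counts pairs per integer percent bin over 80..100 and reports the
#' fraction of pairs at 98--99\% identity, the headline measure of
#' ORF conservation between closely related species.
#'
#' @param identities integer vector of percent identities (NAs dropped).
#' @return list with \code{counts}, a data.frame (\code{percent},
#'   \code{count}) over bins 80..100 (values outside are clamped into the
#'   nearest bin for counting but also tallied in \code{n_below_80}), and
#'   \code{frac_98_99}, the fraction of pairs with identity 98 or 99.
#' @export
similarityHistogram <- function(identities) {
  v <- identities[!is.na(identities)]
  counts <- data.frame(percent = 80:100,
                       count = vapply(80:100, function(p) sum(v == p),
                                      integer(1)))
  list(counts = counts,
       n_below_80 = sum(v < 80),
       frac_98_99 = if (length(v)) mean(v %in% c(98L, 99L)) else NA_real_)
}
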