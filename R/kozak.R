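# Kozak start-codon context extraction and consensus profiling.

#' Extract the -4..+4 start-codon context
#'
#' Returns the 8-nt window \code{seq[orfStart-4 .. orfStart+3]}: four
#' bases of 5'UTR, the ATG, and the first base after it. Contexts are
#' unavailable when the 5'UTR is shorter than 4 nt.
#'
#' @param seq DNA sequence string.
#' @param orfStart 1-based position of the initiator ATG.
#' @return 8-character DNA string, or NA when the 5'UTR is too short.
#' @export
extractKozakContext <- function(seq, orfStart) {
  if (orfStart < 5L) return(NA_character_)
  ctx <- substr(seq, orfStart - 4L, orfStart + 3L)
  if (nchar(ctx) < 8L) return(NA_character_)
  ctx
}

#' Kozak contexts for a classified transcript set
#'
#' @param x a \linkS4class{TranscriptSet}.
#' @param calls classification data.frame; rows with a conserved start are
#'   used.
#' @return named character vector of 8-mers; transcripts with a 5'UTR
#'   shorter than 4 nt are NA.
#' @export
kozakContexts <- function(x, calls) {
  ann <- calls[!is.na(calls$conserved_start_pos), , drop = FALSE]
  seqs <- seqStrings(x)
  ctx <- vapply(seq_len(nrow(ann)), function(i)
    extractKozakContext(seqs[[ann$transcript_id[i]]],
                        ann$conserved_start_pos[i]),
    character(1))
  stats::setNames(ctx, ann$transcript_id)
}

#' Build a Kozak consensus profile from extracted contexts
#'
#' Counts bases per position over all usable contexts (NA contexts and
#' contexts containing N are excluded and counted in \code{nExcluded}).
#' Positions +1..+3 must be the start codon A, T, G in every context; any
#' other codon there signals an extraction bug and is an error.
#'
#' @param contexts character vector of 8-nt DNA contexts (NAs allowed).
#' @return A \linkS4class{KozakProfile}.
#' @export
buildKozakProfile <- function(contexts) {
  usable <- contexts[!is.na(contexts) &
                       !grepl("N", contexts, fixed = TRUE)]
  nExcluded <- length(contexts) - length(usable)
  counts <- matrix(0L, nrow = 8L, ncol = 4L,
                   dimnames = list(kozakPositions, c("A", "C", "G", "T")))
  if (length(usable) > 0L) {
    if (any(nchar(usable) != 8L))
      stop("all contexts must be 8 nt")
    if (any(substr(usable, 5L, 7L) != "ATG"))
      stop("context without ATG at positions +1..+3: extraction bug")
    m <- do.call(rbind, strsplit(usable, "", fixed = TRUE))
    for (p in 1:8) {
      tab <- table(factor(m[, p], levels = c("A", "C", "G", "T")))
      counts[p, ] <- as.integer(tab)
    }
  }
  new("KozakProfile", counts = counts,
      nContexts = length(usable), nExcluded = as.integer(nExcluded))
}

#' @rdname KozakProfile-class
#' @param object,x a KozakProfile
#' @export
baseFrequencies <- function(x) {
  if (x@nContexts == 0L) return(x@counts * NA_real_)
  x@counts / x@nContexts
}

#' Per-position information content of a Kozak profile
#'
#' \code{R_i = 2 - H_i}, with \code{H_i} the Shannon entropy in bits of
#' position i's base frequencies. No small-sample correction is applied.
#'
#' @param x a \linkS4class{KozakProfile}.
#' @return numeric vector of length 8, in bits.
#' @export
informationBits <- function(x) {
  f <- baseFrequencies(x)
  H <- apply(f, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  stats::setNames(2 - H, kozakPositions)
}

#' Consensus string of a Kozak profile
#'
#' Modal base per position, ties broken in the fixed order A > C > G > T
#' (tied positions are flagged in the \code{ties} attribute). Reported in
#' RNA alphabet, matching the field's convention for the motif.
#'
#' @param x a \linkS4class{KozakProfile}.
#' @param asRNA report in RNA alphabet (default TRUE).
#' @return 8-character consensus string with a logical \code{ties}
#'   attribute (one flag per position).
#' @export
kozakConsensus <- function(x, asRNA = TRUE) {
  bases <- colnames(x@counts)
  idx <- apply(x@counts, 1L, which.max)     # first max: A > C > G > T order
  tie <- apply(x@counts, 1L, function(r) sum(r == max(r)) > 1L)
  cons <- paste(bases[idx], collapse = "")
  if (asRNA) cons <- dnaToRna(cons)
  attr(cons, "ties") <- stats::setNames(tie, kozakPositions)
  cons
}

#' Write a Kozak profile as a counts matrix (RNA alphabet)
#'
#' @param x a \linkS4class{KozakProfile}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeKozakProfile <- function(x, path) {
  m <- x@counts
  colnames(m) <- c("A", "C", "G", "U")
  df <- data.frame(position = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
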