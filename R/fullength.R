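# Full-length classification: the conserved-start-codon rule and the
# four-part full-length definition (conserved start codon, complete ORF,
# stop codon, poly(A) tail).

#' Select the best translated-search hit for one query
#'
#' Returns the hit with the smallest E-value among hits passing the
#' E-value cutoff; ties are broken by higher percent identity, then by
#' lexicographic subject id. The conventional cutoff for calling a
#' putative full-length cDNA is E < 1e-5.
#'
#' @param hits data.frame of hits (see \code{\link{readBlastTab}}) all
#'   sharing one \code{query_id}.
#' @param eCut E-value cutoff; hits with \code{evalue < eCut} compete.
#' @return A one-row data.frame, or \code{NULL} when no hit passes.
#' @export
selectBestHit <- function(hits, eCut = 1e-5) {
  if (nrow(hits) == 0L) return(NULL)
  if (length(unique(hits$query_id)) > 1L)
    stop("selectBestHit expects hits for a single query; got ",
         length(unique(hits$query_id)))
  pass <- hits[hits$evalue < eCut, , drop = FALSE]
  if (nrow(pass) == 0L) return(NULL)
  ord <- order(pass$evalue, -pass$pct_identity, pass$subject_id,
               method = "radix")
  pass[ord[1L], , drop = FALSE]
}

#' Test for a conserved start codon
#'
#' A transcript encodes a conserved start codon when, in the reading frame
#' of its best translated-search hit, it has an in-frame ATG (a) upstream
#' of the alignment start with no in-frame stop codon between the ATG and
#' the alignment start, (b) at the alignment start when the alignment
#' begins at residue 1 of the reference protein, or (c) inside the
#' alignment at a codon mapping to one of the first \code{maxSubjectAa}
#' residues of the reference. When several ATGs qualify the 5'-most one is
#' reported, giving the maximal ORF.
#'
#' @param seq a DNA sequence string (5'->3').
#' @param hit one-row hit data.frame for this transcript.
#' @param maxSubjectAa reference-protein window, in residues (default 10,
#'   inclusive).
#' @return list with elements \code{conserved} (logical) and \code{pos}
#'   (1-based position of the accepted ATG, or NA).
#' @export
hasConservedStart <- function(seq, hit, maxSubjectAa = 10L) {
  qs <- hit$q_start; qe <- hit$q_end
  ss <- hit$s_start; se <- hit$s_end
  if ((qe - qs + 1L) != 3L * (se - ss + 1L))
    stop("inconsistent hit coordinates for ", hit$query_id,
         ": query span must be 3x the subject span")
  cand <- integer(0)
  # (a) upstream in-frame ATGs, walking 5' until an in-frame stop blocks
  p <- qs - 3L
  while (p >= 1L) {
    cod <- substr(seq, p, p + 2L)
    if (cod %in% STOP_CODONS) break
    if (cod == "ATG") cand <- c(cand, p)
    p <- p - 3L
  }
  # (b) at the alignment start, when aligned from residue 1
  if (ss == 1L && substr(seq, qs, qs + 2L) == "ATG")
    cand <- c(cand, qs)
  # (c) within the alignment, mapping to subject residues <= maxSubjectAa
  aaHi <- min(se, maxSubjectAa)
  if (ss <= aaHi) {
    for (aa in ss:aaHi) {
      p <- qs + 3L * (aa - ss)
      if (substr(seq, p, p + 2L) == "ATG") cand <- c(cand, p)
    }
  }
  if (length(cand) == 0L) return(list(conserved = FALSE, pos = NA_integer_))
  list(conserved = TRUE, pos = min(cand))
}

flStatuses <- c("full_length", "internal_polyA_suspect",
                "missing_conserved_start", "missing_stop",
                "missing_polyA", "no_significant_hit")

#' Classify transcripts as full-length cDNAs
#'
#' Applies the full-length definition to every transcript: a full-length
#' cDNA has a conserved start codon, a complete ORF ending in a stop
#' codon, and a poly(A) tail. Transcripts meeting all criteria but whose
#' 3'UTR (stop codon to tail start) is shorter than \code{minUtr3} with no
#' canonical PAS hexamer in the 35-nt window upstream of the tail are
#' downgraded to \code{internal_polyA_suspect} (the tail is then likely an
#' internal priming artifact, not the true 3' end). Otherwise the first
#' failing criterion, in the order hit, conserved start, stop codon,
#' poly(A), names the status.
#'
#' @param x a \linkS4class{TranscriptSet}.
#' @param hits data.frame of translated-search hits.
#' @param eCut E-value cutoff for significant hits (default 1e-5).
#' @param maxSubjectAa conserved-start window on the reference protein.
#' @param minTail,maxMismatchFrac poly(A) detector settings, see
#'   \code{\link{detectPolyA}}.
#' @param minUtr3 minimum 3'UTR length (nt) below which, absent a
#'   canonical PAS, the tail is judged internal (default 10).
#' @param pasWindow window searched for the canonical PAS (default 35 nt).
#' @return data.frame with one row per transcript: \code{transcript_id},
#'   \code{species}, \code{status}, \code{conserved_start_pos},
#'   \code{best_hit_subject}, \code{evalue}, ORF/UTR coordinates
#'   (\code{orf_start}, \code{orf_end}, \code{orf_len}, \code{utr5_len},
#'   \code{utr3_len}), tail coordinates (\code{tail_start},
#'   \code{tail_len}, \code{trimmed_len}) and \code{reasons}, a
#'   semicolon-separated trace of the rule outcomes.
#' @export
classifyTranscripts <- function(x, hits, eCut = 1e-5, maxSubjectAa = 10L,
                                minTail = 10L, maxMismatchFrac = 0.1,
                                minUtr3 = 10L, pasWindow = 35L) {
  ids <- txIds(x)
  seqs <- seqStrings(x)
  hitSplit <- if (nrow(hits)) split(hits, hits$query_id) else list()
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    out[[i]] <- classifyOne(ids[i], seqs[[i]], hitSplit[[ids[i]]],
                            eCut, maxSubjectAa, minTail, maxMismatchFrac,
                            minUtr3, pasWindow)
  }
  res <- do.call(rbind, out)
  res$species <- x@species[match(res$transcript_id, ids)]
  res[c("transcript_id", "species",
        setdiff(names(res), c("transcript_id", "species")))]
}

classifyOne <- function(id, seq, myHits, eCut, maxSubjectAa,
                        minTail, maxMismatchFrac, minUtr3, pasWindow) {
  reasons <- character(0)
  polya <- detectPolyA(seq, minTail = minTail,
                       maxMismatchFrac = maxMismatchFrac)
  trimmedLen <- if (is.na(polya$tail_start)) nchar(seq) else
    polya$tail_start - 1L
  row <- data.frame(
    transcript_id = id, status = NA_character_,
    conserved_start_pos = NA_integer_, best_hit_subject = NA_character_,
    evalue = NA_real_, orf_start = NA_integer_, orf_end = NA_integer_,
    orf_len = NA_integer_, utr5_len = NA_integer_, utr3_len = NA_integer_,
    tail_start = polya$tail_start, tail_len = polya$tail_len,
    trimmed_len = trimmedLen, reasons = "", stringsAsFactors = FALSE)

  best <- if (is.null(myHits)) NULL else selectBestHit(myHits, eCut = eCut)
  if (is.null(best)) {
    row$status <- "no_significant_hit"
    row$reasons <- paste0("no hit with E<", format(eCut))
    return(row)
  }
  row$best_hit_subject <- best$subject_id
  row$evalue <- best$evalue
  reasons <- c(reasons, sprintf("hit %s E=%g", best$subject_id, best$evalue))

  cs <- hasConservedStart(seq, best, maxSubjectAa = maxSubjectAa)
  if (!cs$conserved) {
    row$status <- "missing_conserved_start"
    row$reasons <- paste(c(reasons, "no conserved start codon"),
                         collapse = "; ")
    return(row)
  }
  row$conserved_start_pos <- cs$pos
  reasons <- c(reasons, sprintf("conserved ATG at %d", cs$pos))

  orf <- annotateOrf(seq, cs$pos, trimmedLen = trimmedLen)
  if (is.na(orf$orf_end)) {
    row$status <- "missing_stop"
    row$reasons <- paste(c(reasons, "no in-frame stop codon"),
                         collapse = "; ")
    return(row)
  }
  row$orf_start <- orf$orf_start; row$orf_end <- orf$orf_end
  row$orf_len <- orf$orf_len
  row$utr5_len <- orf$utr5_len; row$utr3_len <- orf$utr3_len
  reasons <- c(reasons, sprintf("ORF %d-%d", orf$orf_start, orf$orf_end))

  if (is.na(polya$tail_start)) {
    row$status <- "missing_polyA"
    row$reasons <- paste(c(reasons, "no poly(A) tail"), collapse = "; ")
    return(row)
  }
  reasons <- c(reasons, sprintf("poly(A) tail at %d (len %d)",
                                polya$tail_start, polya$tail_len))

  if (orf$utr3_len < minUtr3) {
    win <- substr(seq, max(1L, polya$tail_start - pasWindow),
                  polya$tail_start - 1L)
    if (!grepl("AATAAA", win, fixed = TRUE) &&
        !grepl("ATTAAA", win, fixed = TRUE)) {
      row$status <- "internal_polyA_suspect"
      row$reasons <- paste(c(reasons,
        sprintf("3'UTR %d nt < %d and no PAS: likely internal poly(A)",
                orf$utr3_len, minUtr3)), collapse = "; ")
      return(row)
    }
  }
  row$status <- "full_length"
  row$reasons <- paste(c(reasons, "full-length"), collapse = "; ")
  row
}
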