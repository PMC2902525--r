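# Poly(A) tail detection, PAS calling in the 35-bp upstream window, and
# exhaustive hexamer discovery among non-canonical transcripts.

#' Detect a 3' poly(A) tail
#'
#' The tail is the longest 3'-terminal segment that (i) is at least
#' \code{minTail} nt long, (ii) has an A-fraction of at least
#' \code{1 - maxMismatchFrac}, and (iii) both starts and ends with A (a
#' mismatch base cannot sit on the tail boundary, which keeps the reported
#' tail from absorbing arbitrary upstream sequence).
#'
#' @param seq DNA sequence string.
#' @param minTail minimum tail length in nt (default 10).
#' @param maxMismatchFrac maximum tolerated non-A fraction (default 0.1).
#' @return list with \code{tail_start} (1-based position of the first tail
#'   base, NA when no tail), \code{tail_len} and \code{trimmed_len}
#'   (sequence length after tail removal).
#' @export
detectPolyA <- function(seq, minTail = 10L, maxMismatchFrac = 0.1) {
  n <- nchar(seq)
  none <- list(tail_start = NA_integer_, tail_len = 0L, trimmed_len = n)
  if (n < minTail) return(none)
  revChars <- rev(strsplit(seq, "", fixed = TRUE)[[1L]])
  isA <- revChars == "A"
  if (!isA[1L]) return(none)                 # tail must end the sequence in A
  cumA <- cumsum(isA)
  L <- seq_len(n)
  ok <- L >= minTail & isA & cumA >= (1 - maxMismatchFrac) * L
  if (!any(ok)) return(none)
  len <- max(L[ok])
  list(tail_start = n - len + 1L, tail_len = len, trimmed_len = n - len)
}

#' Extract the PAS search window upstream of a poly(A) tail
#' @param seq DNA sequence string.
#' @param tailStart 1-based position of the first tail base.
#' @param window window size in nt (default 35).
#' @return the (at most) \code{window}-nt substring ending at
#'   \code{tailStart - 1}.
#' @export
pasWindow <- function(seq, tailStart, window = 35L) {
  substr(seq, max(1L, tailStart - window), tailStart - 1L)
}

#' Call the polyadenylation signal for one tailed transcript
#'
#' Screens the (at most) 35-nt window immediately upstream of the poly(A)
#' tail for the canonical PAS hexamers, AAUAAA first and then AUUAAA
#' (canonical-signal precedence). The 3'-most occurrence is recorded, PAS
#' function being position-dependent. Transcripts carrying neither signal
#' are provisionally classed \code{"none"}; \code{\link{resolvePasClasses}}
#' upgrades them to \code{"other"} when a discovered over-represented
#' hexamer lies in their window.
#'
#' @param seq DNA sequence string.
#' @param polya result of \code{\link{detectPolyA}}; the tail must be
#'   present.
#' @param window search window in nt (default 35).
#' @return list with \code{pas_class} (one of \code{"AAUAAA"},
#'   \code{"AUUAAA"}, \code{"none"}), \code{hexamer} (RNA 6-mer or NA) and
#'   \code{offset} (nt between the hexamer's last base and the first tail
#'   base; 0 means adjacent).
#' @export
scanPas <- function(seq, polya, window = 35L) {
  if (is.na(polya$tail_start))
    stop("scanPas requires a detected poly(A) tail")
  win <- pasWindow(seq, polya$tail_start, window)
  winStart <- max(1L, polya$tail_start - window)
  for (dna in c("AATAAA", "ATTAAA")) {
    at <- gregexpr(dna, win, fixed = TRUE)[[1L]]
    if (at[1L] != -1L) {
      pos <- max(at)                          # 3'-most occurrence
      hexEnd <- winStart + pos - 1L + 5L
      return(list(pas_class = dnaToRna(dna), hexamer = dnaToRna(dna),
                  offset = polya$tail_start - hexEnd - 1L))
    }
  }
  list(pas_class = "none", hexamer = NA_character_, offset = NA_integer_)
}

#' PAS calls for a classified transcript set
#'
#' Runs \code{\link{scanPas}} on every transcript with a detected tail,
#' then discovers over-represented hexamers among the non-canonical
#' windows and resolves their class to \code{"other"} or \code{"none"}.
#'
#' @param x a \linkS4class{TranscriptSet}.
#' @param calls classification data.frame from
#'   \code{\link{classifyTranscripts}} (supplies tail coordinates).
#' @param window PAS window in nt (default 35).
#' @param minSupport minimum number of supporting transcripts for a
#'   discovered hexamer (default 30).
#' @return list with \code{calls}, a data.frame (\code{transcript_id},
#'   \code{pas_class}, \code{hexamer}, \code{offset}), and
#'   \code{hexamers}, the \code{\link{discoverHexamers}} table built from
#'   the non-canonical windows.
#' @export
pasCalls <- function(x, calls, window = 35L, minSupport = 30L) {
  seqs <- seqStrings(x)
  tailed <- calls[!is.na(calls$tail_start), , drop = FALSE]
  res <- data.frame(transcript_id = tailed$transcript_id,
                    pas_class = character(nrow(tailed)),
                    hexamer = NA_character_, offset = NA_integer_,
                    stringsAsFactors = FALSE)
  wins <- character(nrow(tailed))
  for (i in seq_len(nrow(tailed))) {
    id <- tailed$transcript_id[i]
    polya <- list(tail_start = tailed$tail_start[i])
    sc <- scanPas(seqs[[id]], polya, window = window)
    res$pas_class[i] <- sc$pas_class
    res$hexamer[i] <- sc$hexamer
    res$offset[i] <- sc$offset
    wins[i] <- pasWindow(seqs[[id]], tailed$tail_start[i], window)
  }
  nonCanon <- res$pas_class == "none"
  hex <- discoverHexamers(wins[nonCanon], minSupport = minSupport)
  res <- resolvePasClasses(res, wins, hex)
  list(calls = res, hexamers = hex)
}

#' Discover over-represented hexamers in PAS windows
#'
#' Exhaustive exact 6-mer discovery (the degenerate case of
#' TEIRESIAS-style pattern discovery at L = W = 6): every window
#' contributes at most 1 to each hexamer it contains, regardless of how
#' many times the hexamer occurs in it. Hexamers supported by at least
#' \code{minSupport} windows are reported in RNA alphabet, sorted by
#' count (descending) then lexicographically.
#'
#' @param windows character vector of DNA window sequences.
#' @param minSupport minimum number of supporting windows (default 30).
#' @return data.frame with columns \code{hexamer} (RNA) and \code{count};
#'   the attribute \code{n_scanned} records the number of windows scanned.
#' @export
discoverHexamers <- function(windows, minSupport = 30L) {
  perWindow <- lapply(windows, function(w) {
    n <- nchar(w)
    if (n < 6L) return(character(0))
    unique(substring(w, seq_len(n - 5L), seq_len(n - 5L) + 5L))
  })
  counts <- table(unlist(perWindow))
  counts <- counts[!grepl("N", names(counts), fixed = TRUE)]
  df <- data.frame(hexamer = dnaToRna(names(counts)),
                   count = as.integer(counts), stringsAsFactors = FALSE)
  df <- df[df$count >= minSupport, , drop = FALSE]
  df <- df[order(-df$count, df$hexamer, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_scanned") <- length(windows)
  df
}

#' Resolve non-canonical PAS classes against a discovered hexamer table
#'
#' Transcripts without a canonical signal are classed \code{"other"} when
#' their window contains a hexamer from the discovered table (the
#' highest-count such hexamer is recorded, ties broken lexicographically),
#' and \code{"none"} otherwise.
#'
#' @param pas data.frame of provisional PAS calls.
#' @param windows DNA windows, aligned with \code{pas} rows.
#' @param hexTable discovered hexamer table.
#' @return the \code{pas} data.frame with classes resolved.
#' @export
resolvePasClasses <- function(pas, windows, hexTable) {
  if (nrow(hexTable) == 0L) return(pas)
  dnaHex <- rnaToDna(hexTable$hexamer)
  for (i in which(pas$pas_class == "none")) {
    present <- which(vapply(dnaHex, grepl, logical(1), x = windows[i],
                            fixed = TRUE))
    if (length(present)) {
      j <- present[1L]                        # table is sorted by rank
      pas$pas_class[i] <- "other"
      pas$hexamer[i] <- hexTable$hexamer[j]
      at <- gregexpr(dnaHex[j], windows[i], fixed = TRUE)[[1L]]
      pas$offset[i] <- nchar(windows[i]) - (max(at) + 5L)
    }
  }
  pas
}
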