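# Simplified UTR regulatory-motif descriptor engine: degenerate (IUPAC)
# core segments with optional spacer ranges, flanked by a
# reverse-complementary stem of configurable length and mismatch
# tolerance, plus an optional unpaired 5' bulge. The engine, not the
# shipped descriptor library, is the tested artifact: the shipped IRE,
# SECIS and ADH_DRE descriptors are deliberately simplified stand-ins for
# the full UTRsite descriptors.

#' Create a motif descriptor
#'
#' A descriptor is one or more IUPAC core segments separated by spacer
#' ranges, optionally flanked by a stem: \code{stemLen} bases immediately
#' 5' of the first segment must be reverse-complementary (up to
#' \code{maxStemMismatch} mismatches) to the \code{stemLen} bases
#' immediately 3' of the last segment. \code{bulge5} is a literal
#' (IUPAC) string required immediately 5' of the 5' stem arm, unpaired
#' (the IRE's bulged C).
#'
#' @param name descriptor name.
#' @param core character vector of IUPAC segments (RNA accepted; stored
#'   as DNA).
#' @param stemLen stem arm length in nt (0 = no stem).
#' @param maxStemMismatch tolerated non-complementary stem positions.
#' @param spacers list of \code{c(min, max)} nt gaps between consecutive
#'   segments; length must be \code{length(core) - 1}.
#' @param targetUtr \code{"utr5"} or \code{"utr3"}.
#' @param bulge5 optional IUPAC string immediately 5' of the stem.
#' @return object of class \code{"MotifDescriptor"} (a validated list).
#' @export
motifDescriptor <- function(name, core, stemLen = 0L, maxStemMismatch = 0L,
                            spacers = list(), targetUtr = "utr3",
                            bulge5 = "") {
  core <- toupper(rnaToDna(core))
  bulge5 <- toupper(rnaToDna(bulge5))
  iupac <- "^[ACGTURYSWKMBDHVN]*$"
  if (any(!grepl(iupac, core)) || !grepl(iupac, bulge5))
    stop("descriptor '", name, "' contains non-IUPAC characters")
  if (any(nchar(core) == 0L)) stop("empty core segment in '", name, "'")
  if (length(spacers) != length(core) - 1L)
    stop("descriptor '", name, "' needs ", length(core) - 1L,
         " spacer range(s)")
  if (stemLen < 0L) stop("stemLen must be >= 0")
  structure(list(name = name, core = core, stemLen = as.integer(stemLen),
                 maxStemMismatch = as.integer(maxStemMismatch),
                 spacers = spacers, targetUtr = match.arg(targetUtr,
                                                          c("utr5", "utr3")),
                 bulge5 = bulge5),
            class = "MotifDescriptor")
}

#' @export
print.MotifDescriptor <- function(x, ...) {
  cat("MotifDescriptor", x$name, "(", x$targetUtr, ")\n")
  cat("  core:", paste(dnaToRna(x$core), collapse = " ... "), "\n")
  if (x$stemLen > 0)
    cat("  stem:", x$stemLen, "bp, <=", x$maxStemMismatch, "mismatch(es)",
        if (nzchar(x$bulge5)) paste0(", 5' bulge ", dnaToRna(x$bulge5)),
        "\n")
  invisible(x)
}

# IUPAC pattern match start positions in a plain DNA subject string.
# Ambiguity codes are interpreted in the pattern only.
iupacMatchStarts <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                fixed = "subject")
  Biostrings::start(m)
}

revCompDna <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

#' Scan a UTR sequence with a motif descriptor
#'
#' Reports every position where the core segments match under IUPAC
#' semantics at an admissible spacing and the flanking stem arms are
#' reverse-complementary with at most the tolerated number of mismatches.
#' The hit span runs from the 5' bulge (or 5' stem arm) through the 3'
#' stem arm. With \code{stemLen = 0} and a single segment the scan
#' reduces to plain degenerate string matching.
#'
#' @param utrSeq UTR sequence string, 5'->3', over \{A,C,G,T,N\} (RNA
#'   accepted).
#' @param descriptor a \code{\link{motifDescriptor}}.
#' @return data.frame with columns \code{motif}, \code{start}, \code{end}
#'   (1-based UTR-local, inclusive) and \code{stem_mismatches}, sorted by
#'   ascending start.
#' @export
scanMotif <- function(utrSeq, descriptor) {
  seq <- toupper(rnaToDna(utrSeq))
  d <- descriptor
  segStarts <- lapply(d$core, iupacMatchStarts, subject = seq)
  placements <- placeSegments(segStarts, nchar(d$core), d$spacers)
  hits <- list()
  bl <- nchar(d$bulge5)
  for (pl in placements) {
    s1 <- pl[1L]
    eL <- pl[length(pl)] + nchar(d$core[length(d$core)]) - 1L
    mm <- 0L
    if (d$stemLen > 0L) {
      a5start <- s1 - d$stemLen
      a3end <- eL + d$stemLen
      if (a5start < 1L || a3end > nchar(seq)) next
      arm5 <- substr(seq, a5start, s1 - 1L)
      arm3 <- substr(seq, eL + 1L, a3end)
      mm <- sum(strsplit(arm5, "", fixed = TRUE)[[1L]] !=
                  strsplit(revCompDna(arm3), "", fixed = TRUE)[[1L]])
      if (mm > d$maxStemMismatch) next
    }
    start <- s1 - d$stemLen - bl
    end <- eL + d$stemLen
    if (bl > 0L) {
      if (start < 1L) next
      bulgeAt <- iupacMatchStarts(d$bulge5,
                                  substr(seq, start, start + bl - 1L))
      if (!identical(bulgeAt, 1L)) next
    }
    hits[[length(hits) + 1L]] <-
      data.frame(motif = d$name, start = start, end = end,
                 stem_mismatches = mm, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L)
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), stem_mismatches = integer(0),
                      stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Enumerate admissible segment placements given per-segment match starts
# and spacer ranges. Returns a list of integer vectors of segment starts.
placeSegments <- function(segStarts, segLens, spacers) {
  if (any(lengths(segStarts) == 0L)) return(list())
  acc <- lapply(segStarts[[1L]], function(s) s)
  if (length(segStarts) > 1L) {
    for (k in 2L:length(segStarts)) {
      rng <- spacers[[k - 1L]]
      nxt <- list()
      for (pl in acc) {
        prevEnd <- pl[length(pl)] + segLens[k - 1L] - 1L
        okStarts <- segStarts[[k]][
          segStarts[[k]] >= prevEnd + 1L + rng[1L] &
          segStarts[[k]] <= prevEnd + 1L + rng[2L]]
        for (s in okStarts) nxt[[length(nxt) + 1L]] <- c(pl, s)
      }
      acc <- nxt
      if (length(acc) == 0L) return(list())
    }
  }
  acc
}

#' Shipped motif descriptors
#'
#' Deliberately simplified stand-ins for three UTR regulatory elements:
#' \itemize{
#'   \item IRE (5'UTR): CAGUGH apical loop on a 5-bp stem with at most 1
#'     mismatch and an unpaired C immediately 5' of the stem.
#'   \item SECIS (3'UTR): AUGA core, AAR apical segment and GA 3' core at
#'     spacings 15-40 and 10-30 nt, on a 7-bp stem with at most 2
#'     mismatches.
#'   \item ADH_DRE (3'UTR): a plain degenerate consensus, no stem.
#' }
#' These are synthetic simplifications for exercising the engine, not the
#' UTRdb/UTRsite descriptors.
#'
#' @return named list of \code{\link{motifDescriptor}} objects.
#' @export
shippedDescriptors <- function() {
  list(
    IRE = motifDescriptor("IRE", core = "CAGUGH", stemLen = 5L,
                          maxStemMismatch = 1L, targetUtr = "utr5",
                          bulge5 = "C"),
    SECIS = motifDescriptor("SECIS", core = c("AUGA", "AAR", "GA"),
                            stemLen = 7L, maxStemMismatch = 2L,
                            spacers = list(c(15L, 40L), c(10L, 30L)),
                            targetUtr = "utr3"),
    ADH_DRE = motifDescriptor("ADH_DRE", core = "RCUGYCAYYYUG",
                              stemLen = 0L, targetUtr = "utr3")
  )
}

#' Read motif descriptors from a config file
#'
#' One descriptor per block (blocks separated by blank lines), lines of
#' the form \code{key: value}. Keys: \code{name}, \code{core}
#' (comma-separated segments), \code{stem_len}, \code{max_stem_mismatch},
#' \code{spacers} (comma-separated \code{min-max} ranges),
#' \code{target_utr}, \code{bulge5}.
#'
#' @param path config file path.
#' @return named list of \code{\link{motifDescriptor}} objects.
#' @export
readMotifDescriptors <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!startsWith(lines, "#")]
  blocks <- split(lines, cumsum(lines == ""))
  out <- list()
  for (b in blocks) {
    b <- b[nzchar(b)]
    if (length(b) == 0L) next
    kv <- strsplit(b, ":", fixed = TRUE)
    keys <- trimws(vapply(kv, `[`, character(1), 1L))
    vals <- trimws(vapply(kv, function(z)
      paste(z[-1L], collapse = ":"), character(1)))
    g <- stats::setNames(vals, keys)
    spacers <- list()
    if (!is.na(g["spacers"]) && nzchar(g["spacers"])) {
      parts <- strsplit(g[["spacers"]], ",", fixed = TRUE)[[1L]]
      spacers <- lapply(parts, function(p)
        as.integer(strsplit(trimws(p), "-", fixed = TRUE)[[1L]]))
    }
    d <- motifDescriptor(
      name = g[["name"]],
      core = trimws(strsplit(g[["core"]], ",", fixed = TRUE)[[1L]]),
      stemLen = if (is.na(g["stem_len"])) 0L else as.integer(g[["stem_len"]]),
      maxStemMismatch = if (is.na(g["max_stem_mismatch"])) 0L else
        as.integer(g[["max_stem_mismatch"]]),
      spacers = spacers,
      targetUtr = if (is.na(g["target_utr"])) "utr3" else g[["target_utr"]],
      bulge5 = if (is.na(g["bulge5"])) "" else g[["bulge5"]])
    out[[d$name]] <- d
  }
  out
}

#' Scan the UTRs of classified transcripts for regulatory motifs
#'
#' Applies each descriptor to its target UTR of every transcript with
#' annotated ORF coordinates. Hit coordinates are UTR-local.
#'
#' @param x a \linkS4class{TranscriptSet}.
#' @param calls classification data.frame with ORF coordinates.
#' @param descriptors list of descriptors (default
#'   \code{\link{shippedDescriptors}}).
#' @return data.frame with columns \code{transcript_id}, \code{utr},
#'   \code{motif}, \code{start}, \code{end}, \code{stem_mismatches}.
#' @export
scanUtrMotifs <- function(x, calls, descriptors = shippedDescriptors()) {
  ann <- calls[!is.na(calls$orf_len), , drop = FALSE]
  seqs <- seqStrings(x)
  res <- list()
  for (i in seq_len(nrow(ann))) {
    id <- ann$transcript_id[i]
    utr5 <- if (ann$utr5_len[i] > 0L)
      substr(seqs[[id]], 1L, ann$utr5_len[i]) else ""
    utr3 <- if (ann$utr3_len[i] > 0L)
      substr(seqs[[id]], ann$orf_end[i] + 1L, ann$trimmed_len[i]) else ""
    for (d in descriptors) {
      target <- if (d$targetUtr == "utr5") utr5 else utr3
      if (!nzchar(target)) next
      h <- scanMotif(target, d)
      if (nrow(h)) {
        h$transcript_id <- id
        h$utr <- d$targetUtr
        res[[length(res) + 1L]] <- h
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(transcript_id = character(0), utr = character(0),
                      motif = character(0), start = integer(0),
                      end = integer(0), stem_mismatches = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[c("transcript_id", "utr", "motif", "start", "end",
        "stem_mismatches")]
}
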