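# Sequence and alignment-table input/output, plus quality trimming.
# Coordinates in files and reports are 1-based inclusive; all conversion
# to and from internal representations is confined to this file.

#' Read transcripts from a FASTA file
#'
#' Reads a (wrapped or single-line) FASTA file into a
#' \linkS4class{TranscriptSet}. Sequences are uppercased and RNA (U) is
#' converted to DNA (T); records that contained U are flagged in the
#' \code{rnaInput} slot. The species label is parsed from a
#' \code{token=value} field in the description line (for example
#' \code{">c001 species=B"}); records without the token get
#' \code{defaultSpecies}.
#'
#' @param path path to a FASTA file.
#' @param speciesToken header token holding the species label.
#' @param defaultSpecies label used when the token is absent.
#' @return A \linkS4class{TranscriptSet}.
#' @export
readTranscripts <- function(path, speciesToken = "species",
                            defaultSpecies = "A") {
  # read as raw strings so RNA input (U) survives until normalization
  dss <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(dss) == 0L) stop("no FASTA records in ", path)
  headers <- names(dss)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids))
    stop("duplicate transcript id in ", path, ": ",
         ids[duplicated(ids)][1L])
  pat <- paste0(".*\\b", speciesToken, "=(\\S+).*")
  species <- ifelse(grepl(pat, headers),
                    sub(pat, "\\1", headers), defaultSpecies)
  raw <- stats::setNames(as.character(dss), ids)
  TranscriptSet(raw, species = species)
}

#' Read transcripts with qualities from a FASTQ file
#'
#' Sanger (Phred+33) FASTQ. Qualities are stored as integer Phred scores
#' for use by \code{\link{qualityTrim}}.
#'
#' @inheritParams readTranscripts
#' @return A \linkS4class{TranscriptSet} with qualities.
#' @export
readTranscriptsFastq <- function(path, speciesToken = "species",
                                 defaultSpecies = "A") {
  qss <- Biostrings::readBStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  if (length(qss) == 0L) stop("no FASTQ records in ", path)
  headers <- names(qss)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids))
    stop("duplicate transcript id in ", path, ": ",
         ids[duplicated(ids)][1L])
  pat <- paste0(".*\\b", speciesToken, "=(\\S+).*")
  species <- ifelse(grepl(pat, headers),
                    sub(pat, "\\1", headers), defaultSpecies)
  qstrings <- as.character(S4Vectors::mcols(qss)$qualities)
  quals <- lapply(qstrings, function(q)
    as.integer(charToRaw(q)) - 33L)          # Sanger Phred+33
  raw <- stats::setNames(as.character(qss), ids)
  TranscriptSet(raw, species = species, quals = quals)
}

#' Write a TranscriptSet to FASTA
#'
#' Headers carry the species as a \code{species=} token so that
#' \code{\link{readTranscripts}} round-trips the set.
#'
#' @param x a \linkS4class{TranscriptSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTranscripts <- function(x, path) {
  dss <- txSeqs(x)
  names(dss) <- paste0(txIds(x), " species=", x@species)
  Biostrings::writeXStringSet(dss, filepath = path, format = "fasta")
  invisible(path)
}

#' Quality-trim transcripts to their longest high-quality run
#'
#' Keeps, for each record, the longest contiguous run of bases whose Phred
#' quality is at least \code{qCut} (the classical Q20 trimming rule applied
#' to finished per-base scores). Records with no qualifying base are
#' dropped from the returned set and reported in the \code{trimInfo}
#' attribute.
#'
#' @param x a \linkS4class{TranscriptSet} with qualities.
#' @param qCut minimum Phred score retained (default 20).
#' @return A \linkS4class{TranscriptSet} of trimmed records. The attribute
#'   \code{trimInfo} is a data.frame with columns \code{transcript_id},
#'   \code{trim_start}, \code{trim_end} (1-based coordinates on the input
#'   sequence; NA when dropped) and \code{kept}.
#' @export
qualityTrim <- function(x, qCut = 20L) {
  if (length(x@quals) == 0L)
    stop("qualityTrim requires per-base quality scores")
  ids <- txIds(x)
  seqs <- seqStrings(x)
  info <- data.frame(transcript_id = ids,
                     trim_start = NA_integer_, trim_end = NA_integer_,
                     kept = FALSE, stringsAsFactors = FALSE)
  out <- character(0); outsp <- character(0); outq <- list()
  for (i in seq_along(ids)) {
    q <- x@quals[[i]]
    ok <- q >= qCut
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    good <- which(r$values)
    if (length(good) == 0L) next
    best <- good[which.max(r$lengths[good])]
    s <- starts[best]; e <- ends[best]
    info$trim_start[i] <- s; info$trim_end[i] <- e; info$kept[i] <- TRUE
    out <- c(out, stats::setNames(substring(seqs[i], s, e), ids[i]))
    outsp <- c(outsp, x@species[i])
    outq[[length(outq) + 1L]] <- q[s:e]
  }
  res <- TranscriptSet(out, species = outsp, quals = outq)
  attr(res, "trimInfo") <- info
  res
}

blastTabColumns <- c("query_id", "subject_id", "pct_identity", "length",
                     "mismatch", "gapopen", "q_start", "q_end",
                     "s_start", "s_end", "evalue", "bitscore")

#' Read translated-search hits in 12-column BLAST tabular format
#'
#' Columns: qid, sid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore (the outfmt-6 dialect). Query coordinates
#' are nucleotide, subject coordinates amino acid. The pipeline assumes
#' 5'->3' oriented cDNA clones, so minus-strand HSPs (qstart > qend) are
#' skipped with a warning rather than reverse-complemented. The reading
#' frame is derived from qstart: \code{frame = (qstart - 1) \%\% 3 + 1}.
#'
#' @param path path to the tab-separated hit file.
#' @return data.frame of hits with an added \code{frame} column.
#' @export
readBlastTab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(emptyHits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("malformed BLAST tabular line ", which(nf != 12L)[1L],
         " in ", path, ": expected 12 fields, got ", nf[nf != 12L][1L])
  m <- do.call(rbind, fields)
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    pct_identity = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    q_start = as.integer(m[, 7L]), q_end = as.integer(m[, 8L]),
    s_start = as.integer(m[, 9L]), s_end = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE)
  bad <- which(is.na(hits$evalue) | is.na(hits$q_start) | is.na(hits$q_end))
  if (length(bad))
    stop("malformed BLAST tabular line ", bad[1L], " in ", path)
  if (any(hits$evalue < 0))
    stop("negative E-value on line ", which(hits$evalue < 0)[1L])
  minus <- hits$q_start > hits$q_end
  if (any(minus)) {
    warning(sum(minus), " minus-strand HSP(s) skipped ",
            "(directional clones assumed)")
    hits <- hits[!minus, , drop = FALSE]
  }
  hits$frame <- (hits$q_start - 1L) %% 3L + 1L
  rownames(hits) <- NULL
  hits
}

emptyHits <- function() {
  df <- data.frame(query_id = character(0), subject_id = character(0),
                   pct_identity = numeric(0), length = integer(0),
                   mismatch = integer(0), gapopen = integer(0),
                   q_start = integer(0), q_end = integer(0),
                   s_start = integer(0), s_end = integer(0),
                   evalue = numeric(0), bitscore = numeric(0),
                   stringsAsFactors = FALSE)
  df$frame <- integer(0)
  df
}

#' Write hits in 12-column BLAST tabular format
#' @param hits data.frame as returned by \code{\link{readBlastTab}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBlastTab <- function(hits, path) {
  utils::write.table(hits[, blastTabColumns], file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
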