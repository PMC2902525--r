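#' @import methods
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet
#'   pairwiseAlignment nucleotideSubstitutionMatrix alignedPattern
#'   alignedSubject width
#' @importFrom S4Vectors mcols
#' @importFrom stats runif rbinom rlnorm rmultinom setNames
#' @importFrom utils read.table write.table packageVersion
NULL

#' TranscriptSet: a set of cDNA sequences with species labels
#'
#' The central sequence container of the package. Wraps a
#' \link[Biostrings]{DNAStringSet} and carries, per transcript, a species
#' label and (optionally) per-base Phred quality scores. Sequences are
#' stored as DNA; any RNA input (U) is converted to T on construction and
#' flagged, and presentation-layer reports convert back to RNA where the
#' field convention is RNA (PAS hexamers, Kozak consensus).
#'
#' @slot sequences DNAStringSet, names are the transcript identifiers.
#' @slot species character vector, one label per transcript (default "A").
#' @slot quals list of integer vectors of Phred scores; empty list when
#'   qualities are absent.
#' @slot rnaInput logical vector flagging records that contained U on input.
#'
#' @aliases TranscriptSet-class
#' @export
setClass("TranscriptSet",
  representation(
    sequences = "DNAStringSet",
    species   = "character",
    quals     = "list",
    rnaInput  = "logical"
  )
)

setValidity("TranscriptSet", function(object) {
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (n > 0 && (is.null(ids) || any(ids == "")))
    return("all sequences must be named with transcript ids")
  if (anyDuplicated(ids))
    return(paste0("duplicate transcript id: ",
                  ids[duplicated(ids)][1L]))
  if (n > 0 && any(Biostrings::width(object@sequences) == 0L))
    return("empty sequences are not allowed")
  if (length(object@species) != n)
    return("species must have one label per transcript")
  if (length(object@rnaInput) != n)
    return("rnaInput must have one flag per transcript")
  if (length(object@quals) > 0) {
    if (length(object@quals) != n)
      return("quals, when present, must have one element per transcript")
    wl <- vapply(object@quals, length, integer(1))
    if (any(wl != Biostrings::width(object@sequences)))
      return("quality vectors must match sequence lengths")
  }
  TRUE
})

#' Construct a TranscriptSet
#'
#' @param sequences named character vector or DNAStringSet of DNA/RNA
#'   sequences (5'->3'). RNA is converted to DNA and flagged.
#' @param species character vector of species labels, recycled to length;
#'   default "A".
#' @param quals optional list of integer Phred score vectors, one per
#'   sequence.
#' @return A \linkS4class{TranscriptSet}.
#' @examples
#' ts <- TranscriptSet(c(t1 = "ATGAAATAA"), species = "A")
#' txIds(ts)
#' @export
TranscriptSet <- function(sequences, species = "A", quals = NULL) {
  if (is.character(sequences)) {
    raw <- toupper(sequences)
  } else {
    raw <- toupper(as.character(sequences))
    if (!is.null(names(sequences)) && is.null(names(raw)))
      names(raw) <- names(sequences)
  }
  rna <- grepl("U", raw, fixed = TRUE)
  raw <- chartr("U", "T", raw)
  bad <- grepl("[^ACGTN]", raw)
  if (any(bad))
    stop("sequence ", names(raw)[bad][1L],
         " contains characters outside {A,C,G,T,N,U}")
  dss <- Biostrings::DNAStringSet(raw)
  names(dss) <- names(raw)
  n <- length(dss)
  new("TranscriptSet",
      sequences = dss,
      species   = rep_len(as.character(species), n),
      quals     = if (is.null(quals)) list() else quals,
      rnaInput  = rna)
}

#' @describeIn TranscriptSet-class number of transcripts
#' @param x a TranscriptSet
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@sequences))

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object), "transcripts\n")
  if (length(object) > 0) {
    tab <- table(object@species)
    cat("  species:",
        paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
    w <- Biostrings::width(object@sequences)
    cat(sprintf("  lengths: %d-%d nt (mean %.0f)\n",
                min(w), max(w), mean(w)))
    cat("  qualities:",
        if (length(object@quals)) "present" else "absent", "\n")
  }
})

#' @rdname TranscriptSet
#' @param x a TranscriptSet
#' @export
txIds <- function(x) names(x@sequences)

#' @rdname TranscriptSet
#' @export
txSpecies <- function(x) stats::setNames(x@species, txIds(x))

#' @rdname TranscriptSet
#' @export
txSeqs <- function(x) x@sequences

#' @rdname TranscriptSet
#' @export
txQuals <- function(x) {
  if (length(x@quals)) stats::setNames(x@quals, txIds(x)) else NULL
}

#' Sequences of a TranscriptSet as a plain character vector
#' @param x a TranscriptSet
#' @return named character vector
#' @export
seqStrings <- function(x) {
  stats::setNames(as.character(x@sequences), txIds(x))
}

#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, txIds(x))
  new("TranscriptSet",
      sequences = x@sequences[i],
      species   = x@species[i],
      quals     = if (length(x@quals)) x@quals[i] else list(),
      rnaInput  = x@rnaInput[i])
})

#' KozakProfile: start-codon context profile
#'
#' Base counts, frequencies and per-position information content for the
#' 8-nt window spanning positions -4..+4 around the initiator ATG
#' (positions -4,-3,-2,-1,+1,+2,+3,+4; the start codon occupies +1..+3).
#'
#' @slot counts 8 x 4 integer matrix of base counts; rows are the context
#'   positions, columns A, C, G, T.
#' @slot nContexts number of contexts counted.
#' @slot nExcluded number of annotated transcripts whose context could not
#'   be extracted (5'UTR shorter than 4 nt, or N in the window).
#'
#' @aliases KozakProfile-class
#' @export
setClass("KozakProfile",
  representation(
    counts    = "matrix",
    nContexts = "integer",
    nExcluded = "integer"
  )
)

setValidity("KozakProfile", function(object) {
  if (!identical(dim(object@counts), c(8L, 4L)))
    return("counts must be an 8 x 4 matrix")
  if (!identical(colnames(object@counts), c("A", "C", "G", "T")))
    return("counts columns must be A, C, G, T")
  if (any(object@counts < 0))
    return("counts must be non-negative")
  if (object@nContexts > 0) {
    if (any(rowSums(object@counts) != object@nContexts))
      return("each position's counts must sum to nContexts")
  }
  TRUE
})

setMethod("show", "KozakProfile", function(object) {
  cat("KozakProfile from", object@nContexts, "contexts (",
      object@nExcluded, "excluded )\n")
  if (object@nContexts > 0) {
    cat("  consensus (RNA):", kozakConsensus(object), "\n")
    cat("  information (bits):",
        paste(sprintf("%.2f", informationBits(object)), collapse = " "),
        "\n")
  }
})

kozakPositions <- c("-4", "-3", "-2", "-1", "+1", "+2", "+3", "+4")
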