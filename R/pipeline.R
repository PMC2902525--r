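# End-to-end pipeline: chains classification, ORF/UTR characterization,
# PAS calling, Kozak profiling, motif scanning and the two-species
# comparison, writing TSV reports and a run manifest. The package's
# functions are the programmatic interface; runPipeline() is the
# one-call entry point over a FASTA (or pair of FASTAs) plus a hit table.

#' Run the full-length cDNA analysis pipeline
#'
#' Reads transcripts and translated-search hits, classifies every
#' transcript, and writes stage reports to \code{outDir}:
#' \code{classification.tsv}, \code{length_summary.tsv} and histograms,
#' \code{pas_calls.tsv}, \code{hexamer_table.tsv},
#' \code{kozak_counts.tsv}, \code{motif_hits.tsv} and, when two species
#' are present, \code{ortholog_pairs.tsv} and
#' \code{similarity_histogram.tsv}, plus \code{manifest.tsv} recording
#' parameters, input checksums and per-stage record counts.
#'
#' @param fasta path(s) to input FASTA (one file with species tokens, or
#'   two files whose transcripts get species "A" and "B").
#' @param hitsFile path to the 12-column BLAST tabular hit file.
#' @param outDir output directory.
#' @param stages subset of
#'   \code{c("classify", "characterize", "pas", "kozak", "motifs",
#'   "compare")} to run (classification always runs, the rest depend on
#'   it).
#' @param eCut,minTail,maxMismatchFrac,minUtr3,pasWindow,minSupport
#'   stage thresholds, see the stage functions.
#' @param descriptors motif descriptors for the motif stage.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(fasta, hitsFile, outDir,
                        stages = c("classify", "characterize", "pas",
                                   "kozak", "motifs", "compare"),
                        eCut = 1e-5, minTail = 10L, maxMismatchFrac = 0.1,
                        minUtr3 = 10L, pasWindow = 35L, minSupport = 30L,
                        descriptors = shippedDescriptors()) {
  for (f in c(fasta, hitsFile))
    if (!file.exists(f)) stop("missing input: ", f)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- match.arg(stages, several.ok = TRUE)
  if (length(fasta) == 1L) {
    ts <- readTranscripts(fasta)
  } else {
    a <- readTranscripts(fasta[1L], defaultSpecies = "A")
    b <- readTranscripts(fasta[2L], defaultSpecies = "B")
    ts <- TranscriptSet(c(seqStrings(a), seqStrings(b)),
                        species = c(rep("A", length(a)),
                                    rep("B", length(b))))
  }
  hits <- readBlastTab(hitsFile)
  res <- list()
  params <- c(e_cut = eCut, min_tail = minTail,
              max_mismatch_frac = maxMismatchFrac, min_utr3 = minUtr3,
              pas_window = pasWindow, min_support = minSupport)

  calls <- classifyTranscripts(ts, hits, eCut = eCut, minTail = minTail,
                               maxMismatchFrac = maxMismatchFrac,
                               minUtr3 = minUtr3, pasWindow = pasWindow)
  res$calls <- calls
  writeTsv(calls, file.path(outDir, "classification.tsv"), params)

  if ("characterize" %in% stages) {
    res$summary <- summarizeLengths(calls)
    s <- res$summary
    writeTsv(data.frame(metric = c("n", "mean_seq_len", "mean_orf_len",
                                   "mean_utr3_len"),
                        value = c(s$n, s$mean_seq_len, s$mean_orf_len,
                                  s$mean_utr3_len)),
             file.path(outDir, "length_summary.tsv"), params)
    writeTsv(s$orf_hist, file.path(outDir, "orf_histogram.tsv"), params)
    writeTsv(s$utr3_hist, file.path(outDir, "utr3_histogram.tsv"), params)
  }
  if ("pas" %in% stages) {
    res$pas <- pasCalls(ts, calls, window = pasWindow,
                        minSupport = minSupport)
    writeTsv(res$pas$calls, file.path(outDir, "pas_calls.tsv"), params)
    writeTsv(res$pas$hexamers, file.path(outDir, "hexamer_table.tsv"),
             params)
  }
  if ("kozak" %in% stages) {
    res$kozak <- buildKozakProfile(kozakContexts(ts, calls))
    writeKozakProfile(res$kozak, file.path(outDir, "kozak_counts.tsv"))
  }
  if ("motifs" %in% stages) {
    res$motifs <- scanUtrMotifs(ts, calls, descriptors)
    writeTsv(res$motifs, file.path(outDir, "motif_hits.tsv"), params)
  }
  sp <- txSpecies(ts)
  if ("compare" %in% stages && length(unique(sp)) == 2L) {
    labs <- sort(unique(sp))
    callsA <- calls[calls$species == labs[1L], , drop = FALSE]
    callsB <- calls[calls$species == labs[2L], , drop = FALSE]
    pairs <- pairByIdentity(callsA, callsB)
    pairs <- orthologIdentities(pairs, ts[sp == labs[1L]], callsA,
                                ts[sp == labs[2L]], callsB)
    res$pairs <- pairs
    res$orfSimilarity <- similarityHistogram(pairs$orf_identity)
    writeTsv(pairs, file.path(outDir, "ortholog_pairs.tsv"), params)
    writeTsv(res$orfSimilarity$counts,
             file.path(outDir, "similarity_histogram.tsv"), params)
  }
  writeManifest(outDir, fasta, hitsFile, params, calls)
  invisible(res)
}

# Report writer: a commented header echoing thresholds, then TSV.
writeTsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(paste0("# ", paste(names(params), unname(params),
                                  sep = "=", collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

writeManifest <- function(outDir, fasta, hitsFile, params, calls) {
  statusCounts <- table(factor(calls$status, levels = flStatuses))
  rows <- data.frame(
    key = c("tool_version",
            paste0("param_", names(params)),
            paste0("md5_", basename(c(fasta, hitsFile))),
            "n_input",
            paste0("n_", names(statusCounts))),
    value = c(as.character(utils::packageVersion("flcDNA")),
              as.character(unname(params)),
              unname(tools::md5sum(c(fasta, hitsFile))),
              nrow(calls),
              as.character(as.integer(statusCounts))),
    stringsAsFactors = FALSE)
  writeTsv(rows, file.path(outDir, "manifest.tsv"))
}
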