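# Synthetic two-species transcript sets with full ground truth, so that
# every pipeline stage is testable without external data. Transcripts are
# assembled as utr5 + ORF(ATG ... stop, no internal stop) + utr3 (PAS
# hexamer planted in the 35-nt pre-tail window) + poly(A) tail. The
# generator enforces the boundary conditions that make truth recovery
# well-defined: the tail is pure A (15-30 nt), the bases between the
# planted hexamer and the tail are A-free, A-runs of 6+ in the 3'UTR body
# are broken, spurious canonical PAS hexamers are scrubbed from the
# window, and the 5'UTR carries no unblocked in-frame ATG.

BASES <- c("A", "C", "G", "T")

senseCodons <- function() {
  all64 <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all64, STOP_CODONS)
}

# Table-2-style non-canonical hexamer pool (DNA), weighted as observed.
nonCanonicalHexamers <- function() {
  c(TATAAA = 48, AAAAAA = 43, ATAAAA = 40, TGTTTT = 38, TAAAAA = 38,
    AAAAAC = 34, TTTTTG = 33, TTTAAA = 33, AGTAAA = 32, AATATA = 30)
}

#' Synthetic-dataset configuration
#'
#' Defaults emulate a two-species full-length cDNA resource: ORF lengths
#' lognormal with mean about 689 bp clipped to [114, 1416] and rounded to
#' whole codons; 3'UTRs with mean about 243 nt (minimum 45 nt so the
#' 35-nt PAS window lies inside the UTR); short 5'UTRs (mean about 30
#' nt); Kozak contexts drawn from a position-frequency model whose modal
#' string is AAACATGG; canonical PAS frequencies 0.55 (AATAAA) and 0.26
#' (ATTAAA) with the remaining 0.19 spread over ten observed non-canonical
#' hexamers in proportion to their reported support; ortholog divergence
#' 0.015 substitutions/site in ORFs and 0.05 in UTRs; 416 gene identities
#' shared between the species.
#'
#' @param nA,nB transcripts per species.
#' @param nShared gene identities present in both species.
#' @param seed RNG seed (mandatory; the simulation is fully deterministic
#'   given the seed).
#' @param orfMeanLog,orfSdLog lognormal parameters of ORF length.
#' @param orfRange clip range for ORF length (bp, stop included).
#' @param utr3MeanLog,utr3SdLog,utr3Min 3'UTR length model.
#' @param utr5MeanLog,utr5SdLog,utr5Range 5'UTR length model.
#' @param shortUtr5Frac fraction of transcripts with a 5'UTR under 4 nt
#'   (too short for Kozak context extraction).
#' @param kozakPwm 5 x 4 probability matrix (rows: positions -4..-1 and
#'   +4; columns A, C, G, T).
#' @param pasFreqs named DNA hexamer probabilities; must sum to at most 1
#'   (remainder = no planted signal).
#' @param tailRange poly(A) tail length range (pure A).
#' @param divOrf,divUtr ortholog substitution rates per site.
#' @param orfRateMix optional list(rates=, probs=) replacing the single
#'   \code{divOrf} with a mixture over pairs (used to emulate a broader
#'   observed similarity distribution).
#' @param defectRates named rates for decoy transcripts:
#'   \code{missing_polyA}, \code{missing_stop}, \code{internal_polyA},
#'   \code{no_hit}, \code{missing_conserved_start}; the remainder are
#'   full length.
#' @return validated list of class \code{"SynthConfig"}.
#' @export
synthConfig <- function(nA = 500L, nB = 450L, nShared = 416L, seed,
                        orfMeanLog = log(689) - 0.45^2 / 2,
                        orfSdLog = 0.45, orfRange = c(114L, 1416L),
                        utr3MeanLog = log(243) - 0.6^2 / 2,
                        utr3SdLog = 0.6, utr3Min = 45L,
                        utr5MeanLog = log(30) - 0.5^2 / 2,
                        utr5SdLog = 0.5, utr5Range = c(4L, 150L),
                        shortUtr5Frac = 0.05,
                        kozakPwm = defaultKozakPwm(),
                        pasFreqs = defaultPasFreqs(),
                        tailRange = c(15L, 30L),
                        divOrf = 0.015, divUtr = 0.05,
                        orfRateMix = NULL,
                        defectRates = c(missing_polyA = 0, missing_stop = 0,
                                        internal_polyA = 0, no_hit = 0,
                                        missing_conserved_start = 0)) {
  if (missing(seed)) stop("synthConfig requires a seed")
  if (nShared > min(nA, nB))
    stop("nShared cannot exceed the smaller species set")
  if (sum(pasFreqs) > 1 + 1e-9) stop("pasFreqs must sum to at most 1")
  if (any(pasFreqs < 0)) stop("pasFreqs must be non-negative")
  if (!identical(dim(kozakPwm), c(5L, 4L)))
    stop("kozakPwm must be 5 positions x 4 bases")
  if (any(abs(rowSums(kozakPwm) - 1) > 1e-9))
    stop("kozakPwm rows must sum to 1")
  if (sum(defectRates) > 1) stop("defectRates must sum to at most 1")
  structure(list(nA = as.integer(nA), nB = as.integer(nB),
                 nShared = as.integer(nShared), seed = as.integer(seed),
                 orfMeanLog = orfMeanLog, orfSdLog = orfSdLog,
                 orfRange = orfRange,
                 utr3MeanLog = utr3MeanLog, utr3SdLog = utr3SdLog,
                 utr3Min = as.integer(utr3Min),
                 utr5MeanLog = utr5MeanLog, utr5SdLog = utr5SdLog,
                 utr5Range = utr5Range, shortUtr5Frac = shortUtr5Frac,
                 kozakPwm = kozakPwm, pasFreqs = pasFreqs,
                 tailRange = tailRange, divOrf = divOrf, divUtr = divUtr,
                 orfRateMix = orfRateMix, defectRates = defectRates),
            class = "SynthConfig")
}

#' @rdname synthConfig
#' @export
defaultKozakPwm <- function() {
  pwm <- matrix(0.15, nrow = 5, ncol = 4,
                dimnames = list(c("-4", "-3", "-2", "-1", "+4"), BASES))
  modal <- c("A", "A", "A", "C", "G")       # modal context AAACATGG
  for (i in 1:5) pwm[i, modal[i]] <- 0.55
  pwm
}

#' @rdname synthConfig
#' @export
defaultPasFreqs <- function() {
  other <- nonCanonicalHexamers()
  c(c(AATAAA = 0.55, ATTAAA = 0.26), 0.19 * other / sum(other))
}

randBases <- function(n) {
  if (n <= 0L) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Break runs of >= 6 consecutive A (replace every 6th A of a run with C),
# leaving the protected span [from, to] untouched.
breakARuns <- function(s, protect = NULL) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  run <- 0L
  for (i in seq_along(ch)) {
    prot <- !is.null(protect) && i >= protect[1L] && i <= protect[2L]
    if (ch[i] == "A") {
      run <- run + 1L
      if (run >= 6L && !prot) { ch[i] <- "C"; run <- 0L }
    } else run <- 0L
  }
  paste(ch, collapse = "")
}

# Remove canonical PAS hexamers lying fully inside the last `window` nt
# of utr3, except an occurrence exactly at the protected position (the
# planted signal).
scrubCanonicals <- function(utr3, window = 35L, protectPos = NULL,
                            protectHex = NULL) {
  repeat {
    winStart <- max(1L, nchar(utr3) - window + 1L)
    found <- NULL
    for (hx in c("AATAAA", "ATTAAA")) {
      at <- gregexpr(hx, utr3, fixed = TRUE)[[1L]]
      if (at[1L] == -1L) next
      for (p in at) {
        if (p < winStart) next
        if (!is.null(protectPos) && p == protectPos &&
            identical(hx, protectHex)) next
        found <- p; break
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) return(utr3)
    # mutate one base of the occurrence that lies outside the protected span
    idx <- found:(found + 5L)
    if (!is.null(protectPos))
      idx <- idx[idx < protectPos | idx > protectPos + 5L]
    i <- idx[1L]
    old <- substr(utr3, i, i)
    substr(utr3, i, i) <- if (old == "C") "G" else "C"
  }
}

# Draw a 3'UTR of length len with a hexamer of class `hexamer` (or NA for
# none) planted so that its first base lies `dStart` nt upstream of the
# tail, all bases between hexamer end and tail non-A, and no spurious
# canonical signal in the 35-nt window. Returns list(seq, dStart).
makeUtr3 <- function(len, hexamer) {
  utr3 <- randBases(len)
  if (is.na(hexamer)) {
    utr3 <- breakARuns(utr3)
    utr3 <- scrubCanonicals(utr3)
    dStart <- NA_integer_
    gap <- min(8L, len)
  } else {
    lo <- if (hexamer == "AAAAAA") 14L else 10L
    dStart <- sample(lo:35L, 1L)
    pos <- len - dStart + 1L                 # hexamer start within utr3
    substr(utr3, pos, pos + 5L) <- hexamer
    utr3 <- breakARuns(utr3, protect = c(pos, pos + 5L))
    utr3 <- scrubCanonicals(utr3, protectPos = pos, protectHex = hexamer)
    gap <- dStart - 6L
  }
  # A-free spacer between hexamer end (or UTR tail region) and the tail
  for (i in seq_len(gap)) {
    j <- len - i + 1L
    if (substr(utr3, j, j) == "A")
      substr(utr3, j, j) <- sample(c("C", "G", "T"), 1L)
  }
  list(seq = utr3, dStart = dStart)
}

# Replace in-frame ATG triplets in the 5'UTR (frame anchored at the ORF
# start) so the conserved-start scan cannot walk past the true ATG.
scrubUpstreamAtg <- function(utr5) {
  n <- nchar(utr5)
  p <- n - 2L
  while (p >= 1L) {
    if (substr(utr5, p, p + 2L) == "ATG")
      substr(utr5, p + 1L, p + 1L) <- "C"
    p <- p - 3L
  }
  utr5
}

drawLen <- function(n, meanlog, sdlog, lo, hi) {
  pmin(pmax(round(stats::rlnorm(n, meanlog, sdlog)), lo), hi)
}

#' Mutate a sequence
#'
#' Per-base independent substitution at \code{subRate} (always to one of
#' the three other bases), plus length-1 indels at \code{indelRate}
#' (insertion or deletion with equal probability). Indels default to 0 so
#' ORF mutation preserves the reading frame.
#'
#' @param seq DNA sequence string.
#' @param subRate substitution probability per base, in [0, 1).
#' @param indelRate length-1 indel probability per base, in [0, 1).
#' @param seed optional RNG seed.
#' @return mutated sequence string.
#' @export
mutateSeq <- function(seq, subRate, indelRate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(ch)) < subRate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(BASES, b), 1L), character(1))
  }
  if (indelRate > 0) {
    out <- character(0)
    for (b in ch) {
      if (stats::runif(1) < indelRate) {
        if (stats::runif(1) < 0.5) next                    # deletion
        out <- c(out, b, sample(BASES, 1L))                # insertion
      } else out <- c(out, b)
    }
    ch <- out
  }
  paste(ch, collapse = "")
}

# Mutate ORF interior codon-safely: start and stop codons fixed, mutated
# codons that would become stops are reverted.
mutateOrf <- function(orf, rate) {
  cods <- codonsFrom(orf, 1L)
  n <- length(cods)
  if (n > 2L) {
    for (k in 2L:(n - 1L)) {
      mut <- mutateSeq(cods[k], rate)
      if (!(mut %in% STOP_CODONS)) cods[k] <- mut
    }
  }
  paste(cods, collapse = "")
}

# Assemble one transcript; returns sequence plus its truth row pieces.
buildTranscript <- function(cfg, status, pasHex, sense) {
  orfLen <- drawLen(1L, cfg$orfMeanLog, cfg$orfSdLog,
                    cfg$orfRange[1L], cfg$orfRange[2L])
  orfLen <- as.integer(3L * round(orfLen / 3L))
  nCod <- orfLen %/% 3L
  utr5Len <- if (stats::runif(1) < cfg$shortUtr5Frac) sample(0:3, 1L) else
    as.integer(drawLen(1L, cfg$utr5MeanLog, cfg$utr5SdLog,
                       cfg$utr5Range[1L], cfg$utr5Range[2L]))
  utr3Len <- as.integer(drawLen(1L, cfg$utr3MeanLog, cfg$utr3SdLog,
                                cfg$utr3Min, 2000L))
  # Kozak draw: -4..-1 into the utr5 tail, +4 constrains codon 2
  pwmDraw <- vapply(1:5, function(i)
    sample(BASES, 1L, prob = cfg$kozakPwm[i, ]), character(1))
  cod2pool <- sense[substr(sense, 1L, 1L) == pwmDraw[5L]]
  cods <- c("ATG", sample(cod2pool, 1L),
            if (nCod > 3L) sample(sense, nCod - 3L, replace = TRUE),
            sample(STOP_CODONS, 1L))
  utr5 <- randBases(utr5Len)
  if (utr5Len >= 4L)
    substr(utr5, utr5Len - 3L, utr5Len) <- paste(pwmDraw[1:4],
                                                 collapse = "")
  utr5 <- scrubUpstreamAtg(utr5)

  if (status == "missing_conserved_start") {
    cods[1L] <- "CTG"
    for (k in 2L:min(14L, nCod)) if (cods[k] == "ATG") cods[k] <- "CTG"
  }
  if (status == "missing_stop") {
    # no stop anywhere downstream: fill the utr3 span with sense codons
    extra <- max(1L, round(utr3Len / 3L))
    cods <- c(cods[-length(cods)], sample(sense, extra, replace = TRUE))
    orf <- paste(cods, collapse = "")
    tail <- strrep("A", sample(cfg$tailRange[1L]:cfg$tailRange[2L], 1L))
    seq <- paste0(utr5, orf, tail)
    return(list(seq = seq, orf_start = utr5Len + 1L,
                orf_end = NA_integer_, utr5_len = utr5Len,
                utr3_len = NA_integer_, tail_len = nchar(tail),
                pas_class = NA_character_, pas_hexamer = NA_character_))
  }
  if (status == "internal_polyA") {
    # a 3'UTR under 3 nt would let the tail absorb the stop codon's A
    # (every stop codon contains one), blurring the tail boundary
    utr3Len <- sample(3:9, 1L)
    if (utr3Len < 4L) cods[length(cods)] <- "TAG"
  }
  orf <- paste(cods, collapse = "")
  if (status == "internal_polyA") {
    utr3 <- randBases(utr3Len)
    if (utr3Len > 0L)
      utr3 <- gsub("A", "C", utr3, fixed = TRUE)
    body <- paste0(utr5, orf, utr3)
    # scrub canonical PAS from the 35-nt pre-tail window (codon-safe:
    # mutations land in the third... any base; re-check ORF integrity by
    # only scrubbing within utr3 when possible, else degrade codons to
    # synonymous-free region is unnecessary because the window over the
    # ORF end rarely holds a canonical; handled below)
    body <- scrubWindowCanonicalsCodonSafe(body, utr5Len + 1L,
                                           nchar(paste0(utr5, orf)))
    tail <- strrep("A", sample(cfg$tailRange[1L]:cfg$tailRange[2L], 1L))
    seq <- paste0(body, tail)
    return(list(seq = seq, orf_start = utr5Len + 1L,
                orf_end = utr5Len + orfLen, utr5_len = utr5Len,
                utr3_len = utr3Len, tail_len = nchar(tail),
                pas_class = "none", pas_hexamer = NA_character_))
  }
  u3 <- makeUtr3(utr3Len, pasHex)
  hasTail <- status != "missing_polyA"
  tail <- if (hasTail)
    strrep("A", sample(cfg$tailRange[1L]:cfg$tailRange[2L], 1L)) else ""
  utr3 <- u3$seq
  if (!hasTail && utr3Len > 0L) {
    last <- substr(utr3, utr3Len, utr3Len)
    if (last == "A") substr(utr3, utr3Len, utr3Len) <- "C"
  }
  seq <- paste0(utr5, orf, utr3, tail)
  list(seq = seq, orf_start = utr5Len + 1L, orf_end = utr5Len + orfLen,
       utr5_len = utr5Len, utr3_len = utr3Len, tail_len = nchar(tail),
       pas_class = if (!hasTail) NA_character_ else if (is.na(pasHex))
         "none" else dnaToRna(pasHex),
       pas_hexamer = if (hasTail && !is.na(pasHex)) dnaToRna(pasHex)
         else NA_character_, dStart = u3$dStart)
}

# Scrub canonical hexamers from the pre-tail window when it overlaps the
# ORF: mutated codons must stay sense codons.
scrubWindowCanonicalsCodonSafe <- function(body, orfStart, orfEnd) {
  repeat {
    winStart <- max(1L, nchar(body) - 34L)
    found <- NULL
    for (hx in c("AATAAA", "ATTAAA")) {
      at <- gregexpr(hx, body, fixed = TRUE)[[1L]]
      at <- at[at >= winStart]
      if (length(at) && at[1L] != -1L) { found <- at[1L]; break }
    }
    if (is.null(found)) return(body)
    fixed <- FALSE
    for (i in found:(found + 5L)) {
      for (repl in c("C", "G", "T")) {
        if (substr(body, i, i) == repl) next
        cand <- body
        substr(cand, i, i) <- repl
        if (i >= orfStart && i <= orfEnd) {
          codStart <- orfStart + 3L * ((i - orfStart) %/% 3L)
          cod <- substr(cand, codStart, codStart + 2L)
          if (cod %in% STOP_CODONS) next
          if (codStart == orfStart && cod != "ATG") next
          lastCod <- substr(cand, orfEnd - 2L, orfEnd)
          if (codStart == orfEnd - 2L && !(cod %in% STOP_CODONS) &&
              !(lastCod %in% STOP_CODONS)) next
        }
        body <- cand; fixed <- TRUE; break
      }
      if (fixed) break
    }
    if (!fixed) stop("could not scrub canonical hexamer from window")
  }
}

#' Simulate a two-species full-length cDNA dataset with ground truth
#'
#' See \code{\link{synthConfig}} for the generating model. Returns the
#' combined transcript set, the alignment-hit table standing in for a
#' translated search against a reference protein database, the
#' per-transcript truth table, and the ortholog-pair truth.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return list with \code{transcripts} (\linkS4class{TranscriptSet},
#'   species labels "A"/"B"), \code{hits} (data.frame in the 12-column
#'   tabular dialect plus \code{frame}), \code{truth} (per-transcript
#'   data.frame: id, species, gene, status, coordinates, PAS class and
#'   Kozak context), and \code{pairs} (per shared gene: ids and true
#'   percent identities per region).
#' @export
simulateTranscripts <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$seed)
  sense <- senseCodons()
  statuses <- c("full_length", names(cfg$defectRates))
  probs <- c(1 - sum(cfg$defectRates), unname(cfg$defectRates))
  hexPool <- names(cfg$pasFreqs)
  drawPas <- function() {
    r <- stats::runif(1)
    cum <- cumsum(cfg$pasFreqs)
    k <- match(TRUE, r <= cum)
    if (is.na(k)) NA_character_ else hexPool[k]
  }
  geneIds <- sprintf("SP%05d", seq_len(cfg$nA + cfg$nB - cfg$nShared))

  seqs <- character(0); species <- character(0)
  truth <- list(); hits <- list(); pairRows <- list()
  emit <- function(id, sp, gene, status, tt, seq) {
    seqs[[id]] <<- seq
    species <<- c(species, sp)
    n <- nchar(seq)
    tailStart <- if (tt$tail_len > 0L) n - tt$tail_len + 1L else NA_integer_
    kz <- if (!is.na(tt$orf_end) && tt$utr5_len >= 4L)
      substr(seq, tt$orf_start - 4L, tt$orf_start + 3L) else NA_character_
    truth[[length(truth) + 1L]] <<- data.frame(
      transcript_id = id, species = sp, gene_id = gene,
      status = switch(status, internal_polyA = "internal_polyA_suspect",
                      no_hit = "no_significant_hit", status),
      orf_start = tt$orf_start, orf_end = tt$orf_end,
      utr5_len = tt$utr5_len, utr3_len = tt$utr3_len,
      tail_start = tailStart, tail_len = tt$tail_len,
      trimmed_len = n - tt$tail_len,
      pas_class = tt$pas_class, pas_hexamer = tt$pas_hexamer,
      kozak_context = kz, stringsAsFactors = FALSE)
    if (status != "no_hit") {
      csDecoy <- status == "missing_conserved_start"
      orfEnd <- if (!is.na(tt$orf_end)) tt$orf_end else
        tt$orf_start + 3L * ((n - tt$tail_len - tt$orf_start + 1L) %/% 3L) - 1L
      nCod <- (orfEnd - tt$orf_start + 1L) %/% 3L
      sStart <- if (csDecoy) 15L else 1L
      qStart <- tt$orf_start + 3L * (sStart - 1L)
      sEnd <- nCod - 1L
      qEnd <- qStart + 3L * (sEnd - sStart + 1L) - 1L
      hits[[length(hits) + 1L]] <<- data.frame(
        query_id = id, subject_id = gene,
        pct_identity = round(stats::runif(1, 85, 99), 1),
        length = sEnd - sStart + 1L, mismatch = 0L, gapopen = 0L,
        q_start = qStart, q_end = qEnd, s_start = sStart, s_end = sEnd,
        evalue = 10^stats::runif(1, -50, -6),
        bitscore = round(stats::runif(1, 100, 900), 1),
        stringsAsFactors = FALSE)
    }
  }

  # species A
  partsA <- vector("list", cfg$nA)
  for (i in seq_len(cfg$nA)) {
    status <- sample(statuses, 1L, prob = probs)
    pasHex <- drawPas()
    tt <- buildTranscript(cfg, status, pasHex, sense)
    partsA[[i]] <- c(tt, list(status = status, pasHex = pasHex))
    emit(sprintf("A%05d", i), "A", geneIds[i], status, tt, tt$seq)
  }
  # species B: shared genes are mutated copies of the A transcript
  for (i in seq_len(cfg$nB)) {
    id <- sprintf("B%05d", i)
    if (i <= cfg$nShared) {
      src <- partsA[[i]]
      if (src$status != "full_length") {
        # shared genes stay full length on the B side; rebuild if the A
        # copy is a decoy
        tt <- buildTranscript(cfg, "full_length", src$pasHex, sense)
        src <- c(tt, list(status = "full_length", pasHex = src$pasHex))
      }
      orfA <- substr(src$seq, src$orf_start, src$orf_end)
      utr5A <- substr(src$seq, 1L, src$utr5_len)
      utr3A <- substr(src$seq, src$orf_end + 1L,
                      src$orf_end + src$utr3_len)
      rate <- if (is.null(cfg$orfRateMix)) cfg$divOrf else
        sample(cfg$orfRateMix$rates, 1L, prob = cfg$orfRateMix$probs)
      orfB <- mutateOrf(orfA, rate)
      utr5B <- scrubUpstreamAtg(mutateSeq(utr5A, cfg$divUtr))
      utr3B <- mutateSeq(utr3A, cfg$divUtr)
      # re-impose 3' boundary conditions, replanting the same signal
      if (!is.na(src$pasHex)) {
        pos <- nchar(utr3B) - src$dStart + 1L
        substr(utr3B, pos, pos + 5L) <- src$pasHex
        utr3B <- breakARuns(utr3B, protect = c(pos, pos + 5L))
        utr3B <- scrubCanonicals(utr3B, protectPos = pos,
                                 protectHex = src$pasHex)
        gap <- src$dStart - 6L
      } else {
        utr3B <- breakARuns(utr3B)
        utr3B <- scrubCanonicals(utr3B)
        gap <- min(8L, nchar(utr3B))
      }
      for (k in seq_len(gap)) {
        j <- nchar(utr3B) - k + 1L
        if (substr(utr3B, j, j) == "A")
          substr(utr3B, j, j) <- sample(c("C", "G", "T"), 1L)
      }
      tailB <- strrep("A", sample(cfg$tailRange[1L]:cfg$tailRange[2L], 1L))
      seqB <- paste0(utr5B, orfB, utr3B, tailB)
      ttB <- list(orf_start = nchar(utr5B) + 1L,
                  orf_end = nchar(utr5B) + nchar(orfB),
                  utr5_len = nchar(utr5B), utr3_len = nchar(utr3B),
                  tail_len = nchar(tailB),
                  pas_class = if (is.na(src$pasHex)) "none" else
                    dnaToRna(src$pasHex),
                  pas_hexamer = if (is.na(src$pasHex)) NA_character_ else
                    dnaToRna(src$pasHex))
      emit(id, "B", geneIds[i], "full_length", ttB, seqB)
      # pair truth is only meaningful when the A copy is the emitted,
      # defect-free transcript
      if (partsA[[i]]$status == "full_length")
        pairRows[[length(pairRows) + 1L]] <- data.frame(
        gene_id = geneIds[i], id_A = sprintf("A%05d", i), id_B = id,
        orf_identity_true =
          roundHalfUp(100 * (1 - pDistance(orfA, orfB))),
        utr3_identity_true = if (nchar(utr3A) == nchar(utr3B))
          roundHalfUp(100 * (1 - pDistance(utr3A, utr3B))) else
          NA_integer_,
        stringsAsFactors = FALSE)
    } else {
      status <- sample(statuses, 1L, prob = probs)
      pasHex <- drawPas()
      tt <- buildTranscript(cfg, status, pasHex, sense)
      emit(id, "B", geneIds[cfg$nA + (i - cfg$nShared)], status, tt,
           tt$seq)
    }
  }

  hitsDf <- if (length(hits)) do.call(rbind, hits) else emptyHits()
  if (nrow(hitsDf)) hitsDf$frame <- (hitsDf$q_start - 1L) %% 3L + 1L
  list(transcripts = TranscriptSet(seqs, species = species),
       hits = hitsDf,
       truth = do.call(rbind, truth),
       pairs = if (length(pairRows)) do.call(rbind, pairRows) else NULL)
}

#' Write a simulated dataset to standard files
#'
#' @param sim result of \code{\link{simulateTranscripts}}.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
simulateToFiles <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ts <- sim$transcripts
  sp <- txSpecies(ts)
  paths <- c(
    fasta_A = file.path(dir, "species_A.fasta"),
    fasta_B = file.path(dir, "species_B.fasta"),
    hits = file.path(dir, "hits.tsv"),
    truth = file.path(dir, "truth.tsv"))
  writeTranscripts(ts[sp == "A"], paths["fasta_A"])
  writeTranscripts(ts[sp == "B"], paths["fasta_B"])
  writeBlastTab(sim$hits, paths["hits"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate paralog/allele triples with ground truth
#'
#' Each triple holds two same-species sequences X1, X2 and a cross-species
#' ortholog Y, all derived from one ancestral sequence: for allele
#' triples X2 diverges from X1 at \code{alleleWithin} and Y at
#' \code{cross}; for paralog triples X2 diverges at \code{paralogWithin}
#' (a duplication predating the species split) and Y at \code{cross}.
#' Sequences are substitution-only, so each triple is a gap-free
#' alignment block.
#'
#' @param nAllele,nParalog number of triples of each kind.
#' @param alleleWithin,paralogWithin,cross per-site divergence rates.
#' @param len sequence length.
#' @param seed RNG seed (mandatory).
#' @return list with \code{triples} (list of \code{\link{msaBlock}}s,
#'   taxa X1, X2, Y) and \code{truth} (character vector,
#'   \code{"allelic_variants"} or \code{"paralogs"}).
#' @export
simulateTriples <- function(nAllele, nParalog, alleleWithin = 0.002,
                            paralogWithin = 0.08, cross = 0.02,
                            len = 600L, seed) {
  if (missing(seed)) stop("simulateTriples requires a seed")
  set.seed(seed)
  kinds <- c(rep("allelic_variants", nAllele), rep("paralogs", nParalog))
  triples <- vector("list", length(kinds))
  for (i in seq_along(kinds)) {
    x1 <- randBases(len)
    within <- if (kinds[i] == "paralogs") paralogWithin else alleleWithin
    x2 <- mutateSeq(x1, within)
    y <- mutateSeq(x1, cross)
    triples[[i]] <- msaBlock(c(X1 = x1, X2 = x2, Y = y))
  }
  list(triples = triples, truth = kinds)
}
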