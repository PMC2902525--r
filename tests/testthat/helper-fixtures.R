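# Shared fixture builders: everything is generated in code at test time.

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One-row alignment-hit data.frame with sane defaults.
makeHit <- function(query_id = "q1", subject_id = "S1", q_start, q_end,
                    s_start, s_end, evalue = 1e-20, pct_identity = 95,
                    frame = (q_start - 1L) %% 3L + 1L) {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = pct_identity,
             length = s_end - s_start + 1L, mismatch = 0L, gapopen = 0L,
             q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end,
             evalue = evalue, bitscore = 200, frame = frame,
             stringsAsFactors = FALSE)
}

# Hand-assembled transcript: utr5 + ORF + utr3 + tail, with its matching
# hit (alignment covers the ORF minus the stop codon, from residue 1).
makeTx <- function(id = "t1", utr5 = "CCCC", orfCodons = c("ATG", "AAA",
                   "CCC", "TAA"), utr3 = "GCGCGCGCGCGCGCGCGCGC",
                   tail = strrep("A", 20), evalue = 1e-20) {
  orf <- paste(orfCodons, collapse = "")
  seq <- paste0(utr5, orf, utr3, tail)
  orfStart <- nchar(utr5) + 1L
  nCod <- length(orfCodons)
  hit <- makeHit(query_id = id, q_start = orfStart,
                 q_end = orfStart + 3L * (nCod - 1L) - 1L,
                 s_start = 1L, s_end = nCod - 1L, evalue = evalue)
  list(id = id, seq = seq, hit = hit, orf_start = orfStart,
       orf_end = orfStart + 3L * nCod - 1L)
}

tinyConfig <- function(n, seed, ...) {
  synthConfig(nA = n, nB = n, nShared = 0L, seed = seed, ...)
}
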