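test_that("selectBestHit applies the E-value cut and tie-breaks", {
  h1 <- makeHit(q_start = 1, q_end = 30, s_start = 1, s_end = 10,
                evalue = 1e-3)
  h2 <- makeHit(q_start = 1, q_end = 30, s_start = 1, s_end = 10,
                evalue = 1e-12, subject_id = "S2")
  expect_equal(selectBestHit(rbind(h1, h2))$subject_id, "S2")
  # 1e-4 does not pass a 1e-5 cutoff
  weak <- makeHit(q_start = 1, q_end = 30, s_start = 1, s_end = 10,
                  evalue = 1e-4)
  expect_null(selectBestHit(weak))
  # equal E-values: higher identity wins, then lexicographic subject
  t1 <- makeHit(q_start = 1, q_end = 30, s_start = 1, s_end = 10,
                evalue = 1e-12, pct_identity = 90, subject_id = "SB")
  t2 <- makeHit(q_start = 1, q_end = 30, s_start = 1, s_end = 10,
                evalue = 1e-12, pct_identity = 95, subject_id = "SC")
  t3 <- makeHit(q_start = 1, q_end = 30, s_start = 1, s_end = 10,
                evalue = 1e-12, pct_identity = 95, subject_id = "SA")
  expect_equal(selectBestHit(rbind(t1, t2))$subject_id, "SC")
  expect_equal(selectBestHit(rbind(t2, t3))$subject_id, "SA")
  bad <- rbind(makeHit(query_id = "a", q_start = 1, q_end = 30,
                       s_start = 1, s_end = 10),
               makeHit(query_id = "b", q_start = 1, q_end = 30,
                       s_start = 1, s_end = 10))
  expect_error(selectBestHit(bad), "single query")
})

test_that("conserved start codon rule covers its three cases", {
  # ATG at alignment start with s_start = 1
  tx <- makeTx()
  cs <- hasConservedStart(tx$seq, tx$hit)
  expect_true(cs$conserved)
  expect_equal(cs$pos, tx$orf_start)
  # in-frame ATG 12 nt upstream, no intervening stop, s_start = 15
  utr5 <- paste0("CC", "ATG", "CAACAACAA")   # ATG 12 nt before q_start
  body <- paste(rep("GGG", 30), collapse = "")
  seq <- paste0(utr5, body)
  hit <- makeHit(q_start = nchar(utr5) + 1L,
                 q_end = nchar(utr5) + 30L, s_start = 15L, s_end = 24L)
  cs <- hasConservedStart(seq, hit)
  expect_true(cs$conserved)
  expect_equal(cs$pos, hit$q_start - 12L)
  # an intervening in-frame stop blocks that upstream ATG
  seqBlocked <- paste0("CC", "ATG", "CAATAACAA", body)
  expect_false(hasConservedStart(seqBlocked, hit)$conserved)
  # first in-frame ATG maps to subject residue 12: outside the window
  inner <- paste0(paste(rep("CCC", 11), collapse = ""), "ATG",
                  paste(rep("GGG", 10), collapse = ""))
  hit2 <- makeHit(q_start = 1L, q_end = nchar(inner), s_start = 2L,
                  s_end = 2L + nchar(inner) / 3 - 1L)
  expect_false(hasConservedStart(inner, hit2)$conserved)
  # inconsistent coordinates error
  badHit <- makeHit(q_start = 1, q_end = 29, s_start = 1, s_end = 10)
  expect_error(hasConservedStart(tx$seq, badHit), "3x")
})

test_that("brute-force codon scan reproduces hasConservedStart", {
  # independent oracle: enumerate every in-frame codon position and apply
  # the three qualification rules literally
  oracle <- function(seq, hit, maxAa = 10L) {
    qs <- hit$q_start
    frame0 <- (qs - 1L) %% 3L
    ps <- seq.int(frame0 + 1L, nchar(seq) - 2L, by = 3L)
    ok <- logical(0); pos <- integer(0)
    for (p in ps) {
      if (substr(seq, p, p + 2L) != "ATG") next
      if (p < qs) {
        between <- setdiff(ps[ps > p & ps < qs], integer(0))
        stops <- any(vapply(between, function(b)
          substr(seq, b, b + 2L) %in% STOP_CODONS, logical(1)))
        if (!stops) pos <- c(pos, p)
      } else if (p == qs) {
        if (hit$s_start == 1L) pos <- c(pos, p)
        if (hit$s_start <= maxAa) pos <- c(pos, p)
      } else if (p <= hit$q_end && (p - qs) %% 3L == 0L) {
        aa <- hit$s_start + (p - qs) %/% 3L
        if (aa <= maxAa && aa <= hit$s_end) pos <- c(pos, p)
      }
    }
    if (length(pos) == 0L) list(conserved = FALSE, pos = NA_integer_)
    else list(conserved = TRUE, pos = min(pos))
  }
  set.seed(42)
  STOP_CODONS <- c("TAA", "TAG", "TGA")
  for (i in 1:40) {
    n <- sample(60:200, 1)
    seq <- randSeq(n)
    aaLen <- sample(5:15, 1)
    qs <- sample(1:(n - 3 * aaLen - 2), 1)
    ss <- sample(1:12, 1)
    hit <- makeHit(q_start = qs, q_end = qs + 3 * aaLen - 1,
                   s_start = ss, s_end = ss + aaLen - 1)
    got <- hasConservedStart(seq, hit)
    want <- oracle(seq, hit)
    expect_identical(got, want)
  }
})

test_that("classification applies the four-part definition in gate order", {
  tx <- makeTx(id = "good")
  ts <- TranscriptSet(stats::setNames(tx$seq, "good"))
  calls <- classifyTranscripts(ts, tx$hit)
  expect_equal(calls$status, "full_length")
  expect_equal(calls$conserved_start_pos, tx$orf_start)
  expect_equal(calls$orf_len, 12L)
  expect_equal(calls$utr3_len, 20L)

  # minimal 3'UTR with no PAS: internal poly(A) suspect
  sus <- makeTx(id = "sus", utr3 = "GCGC")
  tsS <- TranscriptSet(stats::setNames(sus$seq, "sus"))
  expect_equal(classifyTranscripts(tsS, sus$hit)$status,
               "internal_polyA_suspect")
  # same short UTR but with a canonical PAS stays full length
  ok <- makeTx(id = "ok", utr3 = "AATAAAGCG")
  tsO <- TranscriptSet(stats::setNames(ok$seq, "ok"))
  expect_equal(classifyTranscripts(tsO, ok$hit)$status, "full_length")

  # gate order: no significant hit trumps everything
  weak <- makeTx(id = "weak", evalue = 1e-4)
  tsW <- TranscriptSet(stats::setNames(weak$seq, "weak"))
  expect_equal(classifyTranscripts(tsW, weak$hit)$status,
               "no_significant_hit")
  # missing stop
  ns <- makeTx(id = "ns", orfCodons = c("ATG", "AAA", "CCC", "GGG"),
               utr3 = "GGGGGGGGGCGGGGGGGGGC")
  tsN <- TranscriptSet(stats::setNames(ns$seq, "ns"))
  expect_equal(classifyTranscripts(tsN, ns$hit)$status, "missing_stop")
  # missing tail
  nt <- makeTx(id = "nt", tail = "")
  tsT <- TranscriptSet(stats::setNames(nt$seq, "nt"))
  expect_equal(classifyTranscripts(tsT, nt$hit)$status, "missing_polyA")
})

test_that("classification is deterministic and monotone in the E cutoff", {
  cfg <- tinyConfig(40, seed = 77)
  sim <- simulateTranscripts(cfg)
  c1 <- classifyTranscripts(sim$transcripts, sim$hits)
  c2 <- classifyTranscripts(sim$transcripts, sim$hits)
  expect_identical(c1, c2)
  # relaxing the cutoff can only add hits: full-length calls survive
  c3 <- classifyTranscripts(sim$transcripts, sim$hits, eCut = 1e-3)
  flIds <- c1$transcript_id[c1$status == "full_length"]
  expect_true(all(c3$status[match(flIds, c3$transcript_id)] ==
                    "full_length"))
})
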