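test_that("a planted IRE is recovered exactly once", {
  set.seed(21)
  arm5 <- "GGCAC"
  ire <- paste0("C", arm5, "CAGTGT", "GTGCC")   # bulge, stem, loop, stem'
  utr <- paste0(randSeq(40), ire, randSeq(40))
  h <- scanMotif(utr, shippedDescriptors()$IRE)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 41L)
  expect_equal(h$end, 41L + nchar(ire) - 1L)
  expect_equal(h$stem_mismatches, 0L)
  # one stem mismatch tolerated, two rejected
  ire1 <- paste0("C", arm5, "CAGTGT", "GTGCG")
  expect_equal(scanMotif(paste0(randSeq(20), ire1, randSeq(20)),
                         shippedDescriptors()$IRE)$stem_mismatches, 1L)
  ire2 <- paste0("C", arm5, "CAGTGT", "GTGGG")
  expect_equal(nrow(scanMotif(paste0(randSeq(20), ire2, randSeq(20)),
                              shippedDescriptors()$IRE)), 0L)
})

test_that("scrambling the IRE context abolishes nearly all hits", {
  set.seed(22)
  ire <- paste0("C", "GGCAC", "CAGTGT", "GTGCC")
  utr <- paste0(randSeq(40), ire, randSeq(40))
  ch <- strsplit(utr, "", fixed = TRUE)[[1L]]
  hits <- vapply(1:100, function(i) {
    nrow(scanMotif(paste(sample(ch), collapse = ""),
                   shippedDescriptors()$IRE))
  }, integer(1))
  expect_gte(mean(hits == 0L), 0.95)
})

test_that("stem-free scanning equals a regular-expression oracle", {
  set.seed(23)
  d <- motifDescriptor("X", "RCUGYCAYYYUG")
  rex <- "[AG]CTG[CT]CA[CT][CT][CT]TG"
  for (i in 1:10) {
    s <- randSeq(400)
    # plant two matches so the comparison is not vacuous
    m1 <- "ACTGCCACCCTG"; m2 <- "GCTGTCATTTTG"
    s <- paste0(substr(s, 1, 100), m1, substr(s, 101, 300), m2,
                substr(s, 301, 400))
    got <- scanMotif(s, d)$start
    at <- gregexpr(rex, s)[[1L]]
    # gregexpr misses overlapping matches; rescan from each position
    want <- which(vapply(seq_len(nchar(s) - 11L), function(p)
      grepl(paste0("^", rex), substr(s, p, p + 11L)), logical(1)))
    expect_identical(got, as.integer(want))
  }
})

test_that("multi-segment descriptors respect spacer ranges", {
  set.seed(24)
  sec <- shippedDescriptors()$SECIS
  arm5 <- "GATCCGA"; arm3 <- "TCGGATC"
  mid1 <- gsub("ATGA|AAA|AA[AG]", "CCCC", randSeq(20))
  mid2 <- gsub("GA", "CC", randSeq(15))
  planted <- paste0(arm5, "ATGA", mid1, "AAA", mid2, "GA", arm3)
  utr <- paste0(randSeq(30), planted, randSeq(30))
  h <- scanMotif(utr, sec)
  expect_gte(nrow(h), 1L)
  expect_true(any(h$start <= 31L & h$end >= 31L + nchar(planted) - 1L))
  # spacer out of range: AAA too close to ATGA
  bad <- paste0(arm5, "ATGA", "CCCCC", "AAA", mid2, "GA", arm3)
  expect_equal(nrow(scanMotif(paste0(randSeq(30), bad, randSeq(30)),
                              sec)), 0L)
  expect_error(motifDescriptor("bad", "ACGZ"), "IUPAC")
})

test_that("descriptor config files round-trip", {
  f <- tempfile()
  writeLines(c("name: IRE", "core: CAGUGH", "stem_len: 5",
               "max_stem_mismatch: 1", "target_utr: utr5", "bulge5: C",
               "",
               "name: SECIS", "core: AUGA, AAR, GA", "stem_len: 7",
               "max_stem_mismatch: 2", "spacers: 15-40, 10-30",
               "target_utr: utr3"), f)
  ds <- readMotifDescriptors(f)
  ship <- shippedDescriptors()
  expect_equal(ds$IRE[names(ds$IRE) != "name"],
               ship$IRE[names(ship$IRE) != "name"],
               ignore_attr = TRUE)
  expect_equal(ds$SECIS$spacers, ship$SECIS$spacers)
})

test_that("UTR scanning reports hits in UTR-local coordinates", {
  set.seed(25)
  ire <- paste0("C", "GGCAC", "CAGTGT", "GTGCC")
  # keep the 5'UTR free of ATG so the conserved start stays at the ORF
  utr5 <- gsub("ATG", "CCC", paste0(randSeq(10), ire, randSeq(5)))
  tx <- makeTx(id = "m1", utr5 = utr5)
  ts <- TranscriptSet(stats::setNames(tx$seq, "m1"))
  calls <- classifyTranscripts(ts, tx$hit)
  hits <- scanUtrMotifs(ts, calls,
                        descriptors = shippedDescriptors()["IRE"])
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 11L)
  expect_equal(hits$utr, "utr5")
})
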