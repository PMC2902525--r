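# Brute-force oracle: try every suffix, apply the tail definition
# literally (length, A-fraction, A at both ends), keep the longest.
polyaOracle <- function(seq, minTail = 10L, maxMismatchFrac = 0.1) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  best <- NA_integer_
  for (len in seq_len(n)) {
    if (len < minTail) next
    sfx <- ch[(n - len + 1L):n]
    if (sfx[1L] != "A" || sfx[len] != "A") next
    if (mean(sfx == "A") < 1 - maxMismatchFrac) next
    best <- len
  }
  if (is.na(best))
    return(list(tail_start = NA_integer_, tail_len = 0L, trimmed_len = n))
  list(tail_start = n - best + 1L, tail_len = best, trimmed_len = n - best)
}

test_that("poly(A) detection matches its worked examples", {
  r <- detectPolyA(paste0("ACGT", strrep("A", 20)))
  expect_equal(r$tail_start, 5L)
  expect_equal(r$tail_len, 20L)
  # 4 terminal A's are below the minimum tail length
  expect_true(is.na(detectPolyA("ACGTAAAA")$tail_start))
  # one interior mismatch tolerated: 29/30 A, ends in A
  withG <- paste0("CCGG", strrep("A", 15), "G", strrep("A", 14))
  r2 <- detectPolyA(withG)
  expect_equal(r2$tail_len, 30L)
  expect_identical(r2, polyaOracle(withG))
})

test_that("poly(A) detection equals the brute-force suffix oracle", {
  set.seed(7)
  for (i in 1:60) {
    seq <- paste0(randSeq(sample(10:60, 1)),
                  strrep("A", sample(0:30, 1)))
    expect_identical(detectPolyA(seq), polyaOracle(seq))
  }
})

test_that("trimming then rescanning finds no tail on simulated data", {
  cfg <- tinyConfig(30, seed = 5)
  sim <- simulateTranscripts(cfg)
  seqs <- seqStrings(sim$transcripts)
  for (i in seq_len(nrow(sim$truth))) {
    tt <- sim$truth[i, ]
    if (tt$tail_len == 0L) next
    trimmed <- substr(seqs[[tt$transcript_id]], 1L, tt$trimmed_len)
    expect_true(is.na(detectPolyA(trimmed)$tail_start))
  }
})

test_that("PAS scanning honors window and canonical precedence", {
  # both canonical signals in the window: AAUAAA wins
  seq <- paste0(randSeq(20), "ATTAAA", "CC", "AATAAA", "GCGCGCGC",
                strrep("A", 20))
  polya <- detectPolyA(seq)
  sc <- scanPas(seq, polya)
  expect_equal(sc$pas_class, "AAUAAA")
  expect_equal(sc$offset, 8L)
  # signal 40 nt upstream of the tail is outside the 35-nt window
  far <- paste0("AATAAA", strrep("G", 40), strrep("A", 20))
  expect_equal(scanPas(far, detectPolyA(far))$pas_class, "none")
  expect_error(scanPas("ACGTACGTACGT", detectPolyA("ACGTACGTACGT")),
               "tail")
  # the 3'-most occurrence is reported
  two <- paste0("AATAAA", "GGGG", "AATAAA", "GCGCGCGC", strrep("A", 15))
  expect_equal(scanPas(two, detectPolyA(two))$offset, 8L)
})

test_that("simulated canonical PAS frequencies are recovered", {
  cfg <- tinyConfig(400, seed = 13)
  sim <- simulateTranscripts(cfg)
  calls <- classifyTranscripts(sim$transcripts, sim$hits)
  pc <- pasCalls(sim$transcripts, calls)
  m <- merge(pc$calls, sim$truth, by = "transcript_id")
  # classes match the planted truth exactly for canonical signals
  can <- m$pas_class.y %in% c("AAUAAA", "AUUAAA")
  expect_true(all(m$pas_class.x[can] == m$pas_class.y[can]))
  n <- nrow(m)
  for (cls in c("AAUAAA", "AUUAAA")) {
    p0 <- if (cls == "AAUAAA") 0.55 else 0.26
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(mean(m$pas_class.x == cls) - p0), 3 * se)
  }
  # every tailed transcript receives exactly one class
  expect_equal(nrow(pc$calls), sum(!is.na(calls$tail_start)))
  expect_true(all(pc$calls$pas_class %in%
                    c("AAUAAA", "AUUAAA", "other", "none")))
})

test_that("hexamer discovery equals the sliding-window dictionary", {
  # independent oracle built as an environment-backed dictionary
  dictOracle <- function(windows) {
    env <- new.env()
    for (w in windows) {
      seen <- character(0)
      for (p in seq_len(max(nchar(w) - 5L, 0L))) {
        h <- substr(w, p, p + 5L)
        if (h %in% seen) next
        seen <- c(seen, h)
        env[[h]] <- (if (is.null(env[[h]])) 0L else env[[h]]) + 1L
      }
    }
    out <- sort(unlist(as.list(env)), decreasing = TRUE)
    out
  }
  # per-window presence counting, not per-occurrence
  expect_equal(discoverHexamers("AAAAAAAA", minSupport = 1L)$count, 1L)
  three <- rep(paste0("GG", "TATAAA", "CC"), 3)
  t3 <- discoverHexamers(three, minSupport = 1L)
  expect_equal(t3$count[t3$hexamer == "UAUAAA"], 3L)
  set.seed(11)
  wins <- vapply(1:60, function(i) randSeq(35), character(1))
  got <- discoverHexamers(wins, minSupport = 2L)
  want <- dictOracle(wins)
  want <- want[want >= 2L]
  gotMap <- stats::setNames(got$count, got$hexamer)
  expect_equal(length(gotMap), length(want))
  expect_equal(unname(gotMap[chartr("T", "U", names(want))]),
               unname(want))
  # empty input gives an empty table
  expect_equal(nrow(discoverHexamers(character(0))), 0L)
})
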