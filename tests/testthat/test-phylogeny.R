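test_that("complete deletion removes exactly the gapped columns", {
  msa <- msaBlock(c(x = "AT-G", y = "ATAG"))
  out <- completeDeletion(msa)
  expect_equal(unclass(out), c(x = "ATG", y = "ATG"),
               ignore_attr = TRUE)
  expect_equal(attr(out, "n_removed"), 1L)
  # gap-free input is untouched
  clean <- msaBlock(c(x = "ACGT", y = "TGCA", z = "ACGA"))
  expect_equal(unclass(completeDeletion(clean)), unclass(clean),
               ignore_attr = TRUE)
  expect_error(completeDeletion(msaBlock(c(x = "-A", y = "A-"))),
               "every column")
  # random blocks against a brute-force column filter
  set.seed(51)
  for (i in 1:20) {
    m <- matrix(sample(c("A", "C", "G", "T", "-"), 60, TRUE,
                       prob = c(0.225, 0.225, 0.225, 0.225, 0.1)),
                nrow = 3)
    rows <- apply(m, 1, paste, collapse = "")
    names(rows) <- c("a", "b", "c")
    keep <- colSums(m == "-") == 0
    if (!any(keep)) next
    want <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
    got <- completeDeletion(msaBlock(rows))
    expect_equal(as.character(got), unname(want))
  }
})

test_that("p-distance and Poisson correction match closed forms", {
  expect_equal(pDistance("AAAA", "AAAA"), 0)
  expect_equal(pDistance("AAAA", "AAAT"), 0.25)
  set.seed(52)
  a <- randSeq(100); b <- randSeq(100)
  want <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) / 100
  expect_equal(pDistance(a, b), want)
  expect_error(pDistance("", ""), "zero-length")

  expect_equal(poissonCorrect(0), 0)
  expect_equal(poissonCorrect(0.5), log(2), tolerance = 1e-12)
  expect_equal(poissonCorrect(0.1), 0.1053605, tolerance = 1e-6)
  expect_error(poissonCorrect(1), "saturated")
  # monotone and >= identity on [0, 1)
  p <- seq(0, 0.95, by = 0.05)
  d <- poissonCorrect(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("neighbor joining recovers additive trees exactly", {
  # worked 4-taxon example: ((a:1,b:2):1,(c:3,d:4))
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighborJoining(dm)
  co <- ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]
  expect_equal(max(abs(co - dm)), 0)
  # topology: a,b form a cherry
  expect_equal(treeBipartitions(tr), "c|d")
  ext <- tr$edge.length[tr$edge[, 2] <= 4]
  names(ext) <- tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]]
  expect_equal(ext[letters[1:4]], c(a = 1, b = 2, c = 3, d = 4))

  # 3 taxa: unique topology, three-point formulas
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighborJoining(d3)
  e3 <- t3$edge.length
  names(e3) <- t3$tip.label[t3$edge[, 2]]
  expect_equal(e3[c("x", "y", "z")], c(x = 0.5, y = 1.5, z = 2.5))

  expect_error(neighborJoining(matrix(c(0, 1, 1, 0), 2, 2,
    dimnames = list(c("p", "q"), c("p", "q")))), ">= 3")
  ns <- dm; ns[1, 2] <- 9
  expect_error(neighborJoining(ns), "symmetric")
})

test_that("NJ reproduces random additive 6-taxon metrics to 1e-9", {
  set.seed(53)
  for (i in 1:100) {
    t0 <- ape::rtree(6)
    t0$edge.length <- runif(nrow(t0$edge), 0.05, 2)
    d0 <- ape::cophenetic.phylo(t0)
    tr <- neighborJoining(d0)
    co <- ape::cophenetic.phylo(tr)[rownames(d0), colnames(d0)]
    expect_lt(max(abs(co - d0)), 1e-9)
  }
})

test_that("NJ agrees with an independent implementation on topology", {
  # hierarchical data: three clades of two taxa each, so the topology is
  # unambiguous (pure-noise matrices can tie the Q-criterion, where
  # different tie-break rules legitimately pick different joins)
  set.seed(54)
  for (i in 1:10) {
    anc <- randSeq(400)
    roots <- vapply(1:3, function(k) mutateSeq(anc, 0.15), character(1))
    taxa <- unlist(lapply(roots, function(r)
      c(mutateSeq(r, 0.03), mutateSeq(r, 0.03))))
    msa <- msaBlock(stats::setNames(taxa, paste0("t", 1:6)))
    D <- pDistanceMatrix(msa)
    mine <- neighborJoining(D)
    theirs <- ape::nj(D)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(theirs)),
                 0, ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are reproducible and saturate on clean signal", {
  # near-zero-homoplasy alignment: two clean clades
  set.seed(55)
  blockA <- randSeq(200)
  blockB <- mutateSeq(blockA, 0.4)
  msa2 <- c(a1 = blockA, a2 = mutateSeq(blockA, 0.01),
            b1 = blockB, b2 = mutateSeq(blockB, 0.01))
  bs <- bootstrapSupport(msaBlock(msa2), nReps = 200, seed = 1)
  expect_equal(unname(bs$support), 100)
  bs2 <- bootstrapSupport(msaBlock(msa2), nReps = 200, seed = 1)
  expect_identical(bs$support, bs2$support)
  expect_error(bootstrapSupport(msaBlock(msa2), nReps = 0), "nReps")
})

test_that("bootstrap supports are stable in the replicate count", {
  set.seed(56)
  anc <- randSeq(400)
  msa <- msaBlock(c(a = mutateSeq(anc, 0.02), b = mutateSeq(anc, 0.02),
                    c = mutateSeq(anc, 0.10), d = mutateSeq(anc, 0.10)))
  s1 <- bootstrapSupport(msa, nReps = 1000, seed = 2)$support
  s2 <- bootstrapSupport(msa, nReps = 5000, seed = 3)$support
  expect_equal(names(s1), names(s2))
  expect_lt(max(abs(s1 - s2)), 2)
})

test_that("the paralog rule follows the distance inequality", {
  set.seed(57)
  anc <- randSeq(600)
  # allele pair at 0.2% within, 2% to the ortholog
  allele <- msaBlock(c(X1 = anc, X2 = mutateSeq(anc, 0.002),
                       Y = mutateSeq(anc, 0.02)))
  va <- callParalog(allele, nReps = 500, seed = 4)
  expect_equal(va$verdict, "allelic_variants")
  expect_lt(va$d_within, va$d_cross_min)
  # pre-speciation duplicate: 8% within, 2% across
  para <- msaBlock(c(X1 = anc, X2 = mutateSeq(anc, 0.08),
                     Y = mutateSeq(anc, 0.02)))
  vp <- callParalog(para, nReps = 500, seed = 4)
  expect_equal(vp$verdict, "paralogs")
  expect_gt(vp$support, 70)
  # anti-symmetry: swapping the within pair against the ortholog flips it
  swapped <- msaBlock(c(X1 = unclass(para)[["X1"]],
                        X2 = unclass(para)[["Y"]],
                        Y = unclass(para)[["X2"]]))
  vs <- callParalog(swapped, nReps = 500, seed = 4)
  expect_equal(vs$verdict, "allelic_variants")
  # saturated distances give an ambiguous flagged verdict
  sat <- msaBlock(c(X1 = strrep("A", 50), X2 = strrep("C", 50),
                    Y = strrep("G", 50)))
  vsat <- callParalog(sat, nReps = 10, seed = 4)
  expect_equal(vsat$verdict, "ambiguous")
  expect_true(vsat$saturated)
})

test_that("unaligned triples are projected onto the first sequence", {
  set.seed(58)
  anc <- randSeq(300)
  x2 <- mutateSeq(anc, 0.01, indelRate = 0.005)
  y <- mutateSeq(anc, 0.03, indelRate = 0.005)
  msa <- alignTripleToFirst(c(X1 = anc, X2 = x2, Y = y))
  expect_equal(length(unique(nchar(unclass(msa)))), 1L)
  v <- callParalog(msa, nReps = 300, seed = 5)
  expect_equal(v$verdict, "allelic_variants")
})
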