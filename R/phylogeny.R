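# Distance phylogenetics: complete deletion, p-distance, Poisson
# correction, neighbor joining, column bootstrap, and the two-species
# paralog-versus-allelic-variant verdict.

#' Construct an alignment block
#'
#' @param seqs named character vector of aligned sequences (protein or
#'   nucleotide), gap character \code{"-"}; all the same length.
#' @return the validated named character vector, classed
#'   \code{"MsaBlock"}.
#' @export
msaBlock <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("aligned sequences must be named")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must all have the same length")
  if (length(seqs) < 2L) stop("an alignment block needs >= 2 sequences")
  structure(toupper(seqs), class = "MsaBlock")
}

#' Remove every column containing a gap (complete deletion)
#'
#' @param msa an \code{\link{msaBlock}} (or named character vector of
#'   equal-length aligned sequences).
#' @return gap-free \code{MsaBlock}; the attribute \code{n_removed}
#'   records how many columns were dropped.
#' @export
completeDeletion <- function(msa) {
  m <- do.call(rbind, strsplit(unclass(msa), "", fixed = TRUE))
  keep <- colSums(m == "-") == 0L
  if (!any(keep)) stop("complete deletion removed every column")
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  res <- msaBlock(stats::setNames(out, names(msa)))
  attr(res, "n_removed") <- sum(!keep)
  res
}

#' Proportion of differing sites between two gap-free aligned sequences
#' @param a,b equal-length gap-free sequence strings.
#' @return p-distance in [0, 1].
#' @export
pDistance <- function(a, b) {
  if (nchar(a) == 0L) stop("zero-length sequences")
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(ca != cb)
}

#' Pairwise p-distance matrix of an alignment block
#' @param msa gap-free \code{\link{msaBlock}}.
#' @return symmetric matrix of p-distances with taxa dimnames.
#' @export
pDistanceMatrix <- function(msa) {
  n <- length(msa)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- pDistance(msa[[i]], msa[[j]])
  }
  D
}

#' Poisson multiple-hit correction
#'
#' \code{d = -log(1 - p)}: the expected number of substitutions per site
#' under a Poisson substitution model, given an observed difference
#' proportion p. Monotone increasing and always at least p.
#'
#' @param p observed difference proportion(s), \code{0 <= p < 1}.
#' @return corrected distance(s).
#' @export
poissonCorrect <- function(p) {
  if (any(p < 0 | p >= 1))
    stop("saturated distance: Poisson correction requires 0 <= p < 1")
  -log(1 - p)
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomerative algorithm: at each step join the pair
#' minimizing the Q-criterion \code{Q_ij = (m-2) d_ij - r_i - r_j};
#' branch lengths from the standard NJ formulas. Exact ties in Q are
#' broken by lexicographic taxon-pair order (internal nodes carry the
#' smallest label among their leaves), making the result deterministic.
#' Negative branch lengths can arise on non-additive input; they are
#' retained and flagged.
#'
#' @param dm symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return an \code{ape} \code{phylo} tree (unrooted; the root node is a
#'   trifurcation). The attribute \code{negativeBranches} flags whether
#'   any branch length is negative.
#' @export
neighborJoining <- function(dm) {
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric")
  taxa <- rownames(dm)
  m <- length(taxa)
  if (m < 3L) stop("neighbor joining needs >= 3 taxa")
  # active nodes carried as newick fragments; labels order tie-breaks
  frag <- taxa
  lab <- taxa
  D <- unname(dm)
  while (m > 3L) {
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      l <- sort(c(lab[ij[1L]], lab[ij[2L]]))
      paste(l, collapse = "\r")
    })
    pick <- cand[order(key, method = "radix")[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmtLen(vi),
                       frag[j], fmtLen(vj))
    newLab <- min(lab[i], lab[j])
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], newFrag)
    lab <- c(lab[keep], newLab)
    m <- m - 1L
  }
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1L], fmtLen(va),
                 frag[2L], fmtLen(vb), frag[3L], fmtLen(vc))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negativeBranches") <- any(tree$edge.length < 0)
  tree
}

fmtLen <- function(x) formatC(x, digits = 17, format = "g")

#' Distance matrix of an alignment block (p-distance, Poisson-corrected)
#' @param msa gap-free \code{\link{msaBlock}}.
#' @param correction \code{"poisson"} (default) or \code{"p"} (raw).
#' @return symmetric distance matrix.
#' @export
distanceMatrix <- function(msa, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  P <- pDistanceMatrix(msa)
  if (correction == "p") return(P)
  D <- P
  D[] <- 0
  off <- upper.tri(P) | lower.tri(P)
  D[off] <- poissonCorrect(P[off])
  D
}

#' Internal bipartitions of an unrooted tree
#'
#' Each internal edge splits the taxa in two; the side not containing the
#' lexicographically smallest taxon is sorted and joined with \code{"|"}.
#' These keys name the supports returned by
#' \code{\link{bootstrapSupport}}.
#'
#' @param phy an \code{ape} \code{phylo} tree.
#' @return character vector of bipartition keys (empty for trees without
#'   internal edges, such as unrooted 3-taxon trees).
#' @export
treeBipartitions <- function(phy) {
  ntip <- length(phy$tip.label)
  anchor <- min(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  below <- vector("list", ntip + phy$Nnode)
  for (t in seq_len(ntip)) below[[t]] <- phy$tip.label[t]
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1L]; chi <- po$edge[k, 2L]
    below[[par]] <- c(below[[par]], below[[chi]])
  }
  keys <- character(0)
  for (k in seq_len(nrow(phy$edge))) {
    chi <- phy$edge[k, 2L]
    if (chi <= ntip) next
    side <- below[[chi]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (anchor %in% side) side <- setdiff(phy$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for the internal edges of the NJ tree
#'
#' Resamples alignment columns with replacement \code{nReps} times,
#' recomputes the Poisson-corrected distance matrix and NJ tree for each
#' replicate, and reports, for each internal bipartition of the reference
#' tree (built from the full alignment), the percentage of replicates
#' containing it.
#'
#' @param msa gap-free \code{\link{msaBlock}} with >= 4 taxa (3-taxon
#'   trees have a single unrooted topology and carry no internal
#'   bipartition).
#' @param nReps number of bootstrap replicates (default 1000).
#' @param seed RNG seed for reproducibility (optional).
#' @return list with \code{tree} (reference NJ tree) and \code{support},
#'   a named numeric vector of percentages keyed by bipartition (taxa on
#'   the side away from the alphabetically first taxon, "|"-joined).
#' @export
bootstrapSupport <- function(msa, nReps = 1000L, seed = NULL) {
  if (nReps < 1L) stop("nReps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  msa <- msaBlock(unclass(msa))
  chars <- do.call(rbind, strsplit(unclass(msa), "", fixed = TRUE))
  ncolA <- ncol(chars)
  taxa <- names(msa)
  n <- length(taxa)
  refTree <- neighborJoining(distanceMatrix(msa))
  refBip <- treeBipartitions(refTree)
  support <- stats::setNames(numeric(length(refBip)), refBip)
  # per-pair mismatch indicators, one column per taxon pair
  pairs <- utils::combn(n, 2L)
  M <- matrix(0, nrow = ncolA, ncol = ncol(pairs))
  for (k in seq_len(ncol(pairs)))
    M[, k] <- chars[pairs[1L, k], ] != chars[pairs[2L, k], ]
  counts <- stats::rmultinom(nReps, size = ncolA,
                             prob = rep(1 / ncolA, ncolA))
  mism <- crossprod(M, counts) / ncolA      # npairs x nReps p-distances
  for (rpl in seq_len(nReps)) {
    P <- matrix(0, n, n, dimnames = list(taxa, taxa))
    p <- pmin(mism[, rpl], 1 - 1e-9)        # guard saturated replicates
    for (k in seq_len(ncol(pairs))) {
      P[pairs[1L, k], pairs[2L, k]] <- P[pairs[2L, k], pairs[1L, k]] <-
        poissonCorrect(p[k])
    }
    bip <- treeBipartitions(neighborJoining(P))
    hit <- refBip %in% bip
    support[hit] <- support[hit] + 1
  }
  list(tree = refTree, support = 100 * support / nReps)
}

#' Align a triple of unaligned sequences onto the first
#'
#' Pairwise Needleman-Wunsch alignment (the package's ortholog-comparison
#' scoring) of the second and third sequence against the first; columns
#' are the first sequence's positions, insertions relative to it are
#' dropped. Complete deletion afterwards removes positions deleted in
#' either projection.
#'
#' @param seqs named character vector of 3 unaligned sequences.
#' @return an \code{\link{msaBlock}} of 3 equal-length rows (may contain
#'   gaps; apply \code{\link{completeDeletion}} before distances).
#' @export
alignTripleToFirst <- function(seqs) {
  stopifnot(length(seqs) == 3L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  ref <- seqs[[1L]]
  proj <- function(other) {
    aln <- Biostrings::pairwiseAlignment(ref, other, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    paste(sa[pa != "-"], collapse = "")
  }
  msaBlock(stats::setNames(c(ref, proj(seqs[[2L]]), proj(seqs[[3L]])),
                           names(seqs)))
}

#' Discriminate paralogs from allelic variants
#'
#' For two highly similar sequences X1, X2 from one species and a
#' putative ortholog Y from the other species: allelic variation within a
#' species should be smaller than the divergence between orthologs of the
#' two species. The verdict compares the Poisson-corrected within-species
#' distance \code{d(X1,X2)} with the smaller of the two cross-species
#' distances. \code{paralogs} when the cross-species distance is smaller
#' (the duplication predates the species split), \code{allelic_variants}
#' when the within-species distance is smaller, \code{ambiguous}
#' otherwise. Support is the percentage of column-bootstrap replicates in
#' which the winning inequality holds (an unrooted 3-taxon tree has no
#' internal bipartition, so the inequality is the operative statistic);
#' verdicts below \code{supportThreshold} are downgraded to
#' \code{ambiguous}.
#'
#' @param msa \code{\link{msaBlock}} of the aligned triple, in the order
#'   X1, X2 (same species), Y (other species); gaps allowed (complete
#'   deletion is applied).
#' @param supportThreshold minimum bootstrap percentage (default 70).
#' @param nReps bootstrap replicates (default 1000).
#' @param seed RNG seed (optional).
#' @return list with \code{verdict}, \code{d_within}, \code{d_cross_min},
#'   \code{support} (percent), \code{saturated} flag and the taxon ids.
#' @export
callParalog <- function(msa, supportThreshold = 70, nReps = 1000L,
                        seed = NULL) {
  stopifnot(length(msa) == 3L)
  if (!is.null(seed)) set.seed(seed)
  msa <- completeDeletion(msa)
  ids <- names(msa)
  chars <- do.call(rbind, strsplit(unclass(msa), "", fixed = TRUE))
  nc <- ncol(chars)
  m12 <- chars[1L, ] != chars[2L, ]
  m1y <- chars[1L, ] != chars[3L, ]
  m2y <- chars[2L, ] != chars[3L, ]
  p12 <- mean(m12); p1y <- mean(m1y); p2y <- mean(m2y)
  base <- list(same_species = ids[1:2], cross_species = ids[3L],
               d_within = NA_real_, d_cross_min = NA_real_,
               support = NA_real_, saturated = FALSE)
  if (max(p12, p1y, p2y) >= 1) {
    base$verdict <- "ambiguous"; base$saturated <- TRUE
    return(base)
  }
  dWithin <- poissonCorrect(p12)
  dCross <- min(poissonCorrect(p1y), poissonCorrect(p2y))
  base$d_within <- dWithin; base$d_cross_min <- dCross
  # bootstrap the inequality; Poisson correction is monotone, so the
  # replicate comparison can be made on p-distances directly
  counts <- stats::rmultinom(nReps, size = nc, prob = rep(1 / nc, nc))
  M <- cbind(m12, m1y, m2y)
  reps <- crossprod(M, counts)              # 3 x nReps mismatch counts
  repWithin <- reps[1L, ]
  repCross <- pmin(reps[2L, ], reps[3L, ])
  if (dCross < dWithin) {
    base$support <- 100 * mean(repCross < repWithin)
    base$verdict <- if (base$support >= supportThreshold) "paralogs"
      else "ambiguous"
  } else if (dWithin < dCross) {
    base$support <- 100 * mean(repWithin < repCross)
    base$verdict <- if (base$support >= supportThreshold)
      "allelic_variants" else "ambiguous"
  } else {
    base$support <- 0
    base$verdict <- "ambiguous"
  }
  base
}
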