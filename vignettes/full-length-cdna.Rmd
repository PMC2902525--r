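---
title: "Identifying and characterizing full-length cDNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and characterizing full-length cDNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flcDNA)
```

## The problem

EST sequencing projects produce large collections of single-pass cDNA
clone reads. Most clones are truncated; the valuable minority carry the
complete transcript in a single insert. This package identifies those
full-length cDNAs and characterizes the resulting resource — length
distributions, translation-initiation (Kozak) context, polyadenylation
signals, UTR regulatory motifs, cross-species conservation, and gene
duplication versus allelic variation — for a pair of closely related
species sequenced side by side.

The input is a set of finished, high-quality consensus sequences per
clone (assembly and base calling are upstream of this package; a Q20
longest-run trimmer is provided for per-base quality scores) together
with translated-search hits against a reference protein database in the
12-column tabular format.

## Full-length classification

A full-length cDNA is defined as a sequence with a conserved start
codon, a complete ORF, a stop codon and a poly(A) tail. The gates are
applied in that order, and the first failure names the status, so the
classification report doubles as a defect census.

**Conserved start codon.** Working in the reading frame of the best hit
(minimum E-value below 1e-5; ties broken by percent identity, then
subject id), an ATG qualifies when it is (a) upstream of the alignment
start with no in-frame stop codon in between — a stop there would make
it unable to initiate the aligned protein; (b) at the alignment start
when the alignment begins at residue 1 of the reference; or (c) inside
the alignment, mapping to one of the first 10 reference residues
(inclusive). When several ATGs qualify, the 5'-most wins, giving the
maximal ORF; this is consistent with preferring the upstream candidate.

**Internal poly(A) artifacts.** Oligo(dT) priming inside A-rich coding
or UTR sequence produces clones whose "tail" is not the true 3' end.
These present as full-length transcripts with almost no 3'UTR. We flag
a transcript as `internal_polyA_suspect` when all four gates pass but
the 3'UTR (stop codon to tail start) is shorter than `minUtr3 = 10` nt
*and* no canonical PAS hexamer lies in the 35-nt pre-tail window. The
threshold is a package choice — the phenomenon is described
qualitatively in the literature without a numeric cutoff — and is
configurable.

**Strand policy.** Minus-strand HSPs (query start beyond query end) are
skipped with a warning rather than reverse-complemented, because
directional, 5'/3'-sequenced clone libraries are assumed.

## Poly(A) tails and polyadenylation signals

No standard defines a poly(A) tail detector; ours is explicit and
configurable: the tail is the longest 3'-terminal segment of length at
least `minTail = 10` whose A-fraction is at least 0.9 **and whose first
and last bases are A**. The boundary condition matters: without it, a
pure 20-A tail preceded by "GT" would absorb those two bases (22-column
segment, 20/22 = 0.91 A), and the reported tail start would creep
upstream without bound as tails lengthen. Requiring A on the boundary
pins the segment to the homopolymer.

The PAS scan then takes the at-most-35-nt window ending immediately
before the tail and screens for AAUAAA first, then AUUAAA (canonical
precedence; the stronger signal wins when both occur). The 3'-most
occurrence is recorded because PAS function is position-dependent.
Windows with neither signal go to hexamer discovery: exhaustive exact
6-mer counting, each transcript contributing at most once per hexamer,
reported above a support threshold (default 30 transcripts) in RNA
alphabet. Exact fixed-length discovery is deliberately the degenerate
case of pattern discovery with length = window = 6, so a sliding-window
dictionary is an exact oracle for it — the test suite uses one.
Discovery runs on the same 35-nt windows as the canonical screen (a
`scope` choice one could widen to the whole 3'UTR; the near-tail window
is the default because that is where functional signals sit).

Sequence is stored as DNA throughout; PAS and Kozak strings are
converted to RNA only at reporting time.

## Kozak context

The 8-nt window from −4 to +4 around the initiator ATG is extracted for
every transcript whose 5'UTR is at least 4 nt (shorter UTRs are counted
as excluded). Contexts containing N are excluded likewise. The profile
holds per-position counts, frequencies, a modal consensus (ties broken
A > C > G > T and flagged) and information content $R_i = 2 - H_i$ bits,
where $H_i$ is the Shannon entropy of position $i$. No small-sample
correction is applied to $R_i$; with the context counts in the hundreds
to thousands the correction is negligible, and only the consensus
string is used downstream.

## UTR motif engine

The motif stage is a deliberately small descriptor engine, not a
reimplementation of a full UTR-site description language: a descriptor
is one or more IUPAC core segments with admissible spacer ranges,
flanked by a reverse-complementary stem of configurable length and
mismatch tolerance, with an optional unpaired 5' bulge. The shipped
IRE (CAGUGH apical loop, 5-bp stem, ≤ 1 mismatch, bulged 5' C), SECIS
(AUGA / AAR / GA cores at 15–40 and 10–30 nt spacings on a 7-bp stem,
≤ 2 mismatches) and ADH_DRE (plain degenerate consensus) descriptors
are simplified stand-ins for exercising the engine; membership of any
particular transcript list is not a claim the package makes. With stem
length 0 and one segment the engine reduces exactly to degenerate
string matching, which gives a regular-expression oracle for testing.
Thermodynamic folding is out of scope.

## Cross-species ortholog comparison

Transcripts of the two species sharing a best-hit gene identity are
paired (one pair per gene; the lowest-E-value transcript represents a
gene with several). Percent identity per region (ORF, 3'UTR) comes
from global alignment with match +1, mismatch −1, linear gap −2, and
free terminal gaps; identity is matches over alignment columns,
excluding columns that are terminal-gap in either sequence, and is
rounded half-up to whole percent. The scoring and the column-exclusion
rule are package choices (reported in the output header); an
HSP-derived identity would differ slightly in gapped regions. The
summary reports counts per integer percent and the fraction of pairs
at 98–99%, the headline conservation measure between closely related
species.

## Paralogs versus allelic variants

Consensus building from two haplotypes inflates apparent gene counts:
two highly similar sequences within one species may be alleles of one
locus or duplicated genes. With a second closely related species, the
discriminating principle is that allelic variation within a species
should be smaller than divergence between orthologs of the two species.
For a triple (X1, X2 same species; Y ortholog), distances are
p-distances after complete deletion of gapped columns, Poisson
corrected, $d = -\ln(1 - p)$: *paralogs* when
$\min(d(X1,Y), d(X2,Y)) < d(X1,X2)$, *allelic variants* for the
opposite inequality.

Support comes from 1,000 column-bootstrap replicates. An unrooted
3-taxon tree has a single topology and no internal bipartition, so
bipartition support is undefined for triples; the operative statistic
is the distance inequality itself, and support is the percentage of
replicates in which it holds (Poisson correction is monotone, so the
replicate comparison is made on p-distances). Verdicts under the 70%
support threshold, and triples with any saturated distance
($p \ge 1$ after complete deletion), are `ambiguous`.

For larger taxon sets the package provides Saitou–Nei neighbor joining
with the standard Q-criterion and branch-length formulas. Exact ties
in Q are broken by lexicographic taxon-pair order (internal nodes
inherit the smallest leaf label), making results deterministic; ties
occur in practice — for four remaining nodes the criterion can tie
exactly — and different valid tie-breaks yield different, equally
optimal joins. Negative branch lengths on non-additive input are
retained and flagged rather than zeroed. Bootstrap supports are
reported per internal bipartition of the reference tree.

## The synthetic-data generator

Every stage is tested against `simulateTranscripts()`, which assembles
transcripts as 5'UTR + ORF + 3'UTR + tail with a complete truth table.
Defaults emulate the study conditions of a two-species full-length
cDNA resource:

* ORF lengths lognormal, mean ≈ 689 bp, clipped to [114, 1416] and
  rounded to whole codons; interiors drawn codon-wise from the 61 sense
  codons so no in-frame stop can occur by construction.
* 3'UTR lengths lognormal, mean ≈ 243 nt, minimum 45 nt (the 35-nt PAS
  window must fit inside the UTR); 5'UTRs short (mean ≈ 30 nt), with
  5% under 4 nt to exercise Kozak exclusion bookkeeping.
* Kozak contexts from a position-frequency model with modal string
  AAACATGG (modal probability 0.55 per position); the +4 base
  constrains the second codon's first base.
* PAS classes at 0.55 AAUAAA, 0.26 AUUAAA, the remaining 0.19 spread
  over ten observed non-canonical hexamers proportional to their
  reported support; the hexamer is planted 10–35 nt upstream of the
  tail.
* Ortholog divergence 0.015 substitutions/site in ORFs and 0.05 in
  UTRs for the 416 shared gene identities (substitution-only, so true
  identities are exact Hamming values); an optional rate mixture
  emulates the broader observed similarity distribution with 74.8% of
  pairs at 98–99%.
* Pure-A tails of 15–30 nt.
* Configurable defect rates produce decoys for each failure mode
  (missing tail, missing stop, internal poly(A), no hit, no conserved
  start).

Closed-loop exactness — the pipeline must recover classification, ORF
coordinates, PAS classes and Kozak contexts *identically* to the truth
table — requires the generator to keep boundaries unambiguous, and
these constraints are part of its design: the bases between the planted
hexamer and the tail are A-free; runs of six or more A in the UTR body
are broken; spurious canonical hexamers are scrubbed from the window
(codon-safely when the window overlaps the ORF, as in internal-poly(A)
decoys); 5'UTRs carry no unblocked in-frame ATG; an all-A planted
hexamer (AAAAAA) is placed at least 14 nt upstream of the tail, and
internal-poly(A) decoys keep at least 3 nt of 3'UTR with a stop codon
ending in G when shorter than 4 — otherwise the tail detector would
legitimately absorb the stop codon's A and the "truth" would be
ill-defined. Tails are capped at 30 nt for the same reason: longer
tails make the 90% A-fraction criterion forgiving enough to swallow an
A-rich hexamer placed at the minimum offset.

What the generator does **not** emulate: realistic codon usage and GC
content, expression levels, alternative splicing or polyadenylation,
sequencing error in the finished consensus, indels between orthologs
(by default), and genuinely ambiguous boundary cases such as tails
interrupted by long non-A stretches. Passing tests therefore
demonstrate algorithmic correctness under the stated model, not
robustness to every artifact of real EST data.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive in all files and reports.
* Report percentages round half away from zero (97.5 → 98).
* `selectBestHit` ties: identity, then lexicographic subject id.
* Kozak consensus ties: fixed base order A > C > G > T, flagged.
* NJ Q-criterion ties: lexicographic taxon-pair order.
* Saturated distances: an error in `poissonCorrect` (the estimate is
  undefined); inside the bootstrap loop replicate p-distances are
  capped just below 1 so a replicate cannot abort a run; `callParalog`
  returns a flagged `ambiguous` verdict when the point estimates
  saturate.
* Empty inputs: classification always yields a status per transcript;
  empty hexamer input yields an empty table; empty regions skip a pair
  with a warning; an empty FASTA is an error.

## Problem sizes in the tests

The suite exercises the closed loop at 2,000 transcripts, PAS frequency
recovery at the same size, hexamer discovery against the dictionary
oracle on 500 windows, Kozak recovery at 1,000 contexts, NJ additivity
on 100 random 6-taxon metrics, and paralog/allele discrimination on
200 triples at 1,000 bootstrap replicates — sizes chosen so the whole
suite runs in about a minute and a half while keeping binomial
tolerances (3 standard errors) meaningful. `scripts/acceptance.R`
re-runs the pipeline at the study scale (1,072 + 695 transcripts, 416
shared genes).

## Known limitations

* The conserved-start rule depends on the reference protein's own
  start annotation; truncated references shift the 10-residue window.
* The internal-poly(A) rule is a heuristic; transcripts with genuinely
  short 3'UTRs and non-canonical signals will be flagged.
* Ortholog pairing by shared best-hit identity conflates paralogous
  assignments when two different genes hit the same reference best.
* The paralog test assumes the triple's alignment is reliable; the
  pairwise-projection aligner drops insertions relative to the first
  sequence and is not a substitute for a proper multiple aligner on
  diverged input.
* Identity from global alignment differs from HSP-local identity on
  sequences with long unalignable ends.
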