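# Small internal helpers shared across modules.

# DNA -> RNA at presentation time only; internal alphabet is always DNA.
dnaToRna <- function(x) chartr("T", "U", x)

rnaToDna <- function(x) chartr("U", "T", x)

# Reports round half away from zero (97.5 -> 98); base round() is half-even.
roundHalfUp <- function(x) floor(x + 0.5)

# Stop codons and the codon table subset we need.
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Split a sequence into consecutive codons starting at `start` (1-based),
# stopping before the last complete codon at or before `end`.
codonsFrom <- function(seq, start, end = nchar(seq)) {
  starts <- seq.int(start, end - 2L, by = 3L)
  if (start > end - 2L) return(character(0))
  substring(seq, starts, starts + 2L)
}

# First in-frame stop codon at or after `start`; NA_integer_ if none
# before `end`. Returns the 1-based position of the stop codon's first base.
firstInFrameStop <- function(seq, start, end = nchar(seq)) {
  cods <- codonsFrom(seq, start, end)
  hit <- match(TRUE, cods %in% STOP_CODONS)
  if (is.na(hit)) return(NA_integer_)
  start + 3L * (hit - 1L)
}
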