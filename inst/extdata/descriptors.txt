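# Simplified UTR motif descriptors (synthetic stand-ins, matching
# shippedDescriptors()). One block per descriptor; key: value lines.

name: IRE
core: CAGUGH
stem_len: 5
max_stem_mismatch: 1
target_utr: utr5
bulge5: C

name: SECIS
core: AUGA, AAR, GA
stem_len: 7
max_stem_mismatch: 2
spacers: 15-40, 10-30
target_utr: utr3

name: ADH_DRE
core: RCUGYCAYYYUG
stem_len: 0
target_utr: utr3
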