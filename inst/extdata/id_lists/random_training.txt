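# 13 background ("random") training identifiers. The original background
# panel was drawn with a random number generator and never published, so this
# list is a SYNTHETIC stand-in frozen here for reproducibility: 13
# piRNAdb-style identifiers, disjoint from the other packaged panels, fixed
# once and never regenerated. Sequences are user-supplied in any case.
piR-000118
piR-001954
piR-002760
piR-004981
piR-006233
piR-008476
piR-010342
piR-012065
piR-013599
piR-015728
piR-018104
piR-019447
piR-021356
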