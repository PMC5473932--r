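# Domain partition for the default synthetic four-domain protein
# (4 domains x 25 residues; tags follow the a-b-bp-ap naming of
# thioredoxin-fold multidomain proteins).
a: [1, 25]
b: [26, 50]
bp: [51, 75]
ap: [76, 100]
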