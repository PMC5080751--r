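# A small mapping-cross scenario: an XY sire locus on the LG5 arm of the
# LG5-14 fusion chromosome, two families, penetrance 0.88.
linkage_groups:
  - lg: LG5
    length_bp: 38000000
    length_morgans: 0.9
  - lg: LG14
    length_bp: 25000000
    length_morgans: 0.6
  - lg: LG13
    length_bp: 34000000
    length_morgans: 0.8
fusions:
  - [LG5, LG14]
loci:
  - lg: LG5
    position: 1900000
    allele: Y
    carrier: sire
    copies: 1
penetrance: 0.88
families:
  - name: famA
    n_offspring: 24
  - name: famB
    n_offspring: 18
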