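name	block_class	formula	hydroxyls
CA	bile_acid	C24H40O5	3
HCA	bile_acid	C24H40O5	3
aMCA	bile_acid	C24H40O5	3
bMCA	bile_acid	C24H40O5	3
CDCA	bile_acid	C24H40O4	2
DCA	bile_acid	C24H40O4	2
UDCA	bile_acid	C24H40O4	2
HDCA	bile_acid	C24H40O4	2
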