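name	block_class	formula	mass_group
Ala	amino_acid	C3H7NO2	
Arg	amino_acid	C6H14N4O2	
Asn	amino_acid	C4H8N2O3	
Asp	amino_acid	C4H7NO4	
Cys	amino_acid	C3H7NO2S	
Gln	amino_acid	C5H10N2O3	
Glu	amino_acid	C5H9NO4	
His	amino_acid	C6H9N3O2	
Ile	amino_acid	C6H13NO2	Ile/Leu
Leu	amino_acid	C6H13NO2	Ile/Leu
Lys	amino_acid	C6H14N2O2	
Met	amino_acid	C5H11NO2S	
Phe	amino_acid	C9H11NO2	
Pro	amino_acid	C5H9NO2	
Ser	amino_acid	C3H7NO3	
Thr	amino_acid	C4H9NO3	
Trp	amino_acid	C11H12N2O2	
Tyr	amino_acid	C9H11NO3	
Val	amino_acid	C5H11NO2	
Cit	amino_acid	C6H13N3O3	
Orn	amino_acid	C5H12N2O2	
DOPA	amino_acid	C9H11NO4	
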