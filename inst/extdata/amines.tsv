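name	block_class	formula	mass_group
methylamine	amine	CH5N	
ethylamine	amine	C2H7N	
propylamine	amine	C3H9N	
butylamine	amine	C4H11N	
isopentylamine	amine	C5H13N	
hexylamine	amine	C6H15N	
ethanolamine	amine	C2H7NO	
phenethylamine	amine	C8H11N	
tyramine	amine	C8H11NO	
tryptamine	amine	C10H12N2	
serotonin	amine	C10H12N2O	
histamine	amine	C5H9N3	
dopamine	amine	C8H11NO2	
octopamine	amine	C8H11NO2	
putrescine	amine	C4H12N2	
cadaverine	amine	C5H14N2	
spermidine	amine	C7H19N3	
agmatine	amine	C5H14N4	
GABA	amine	C4H9NO2	
beta-alanine	amine	C3H7NO2	
glycine	amine	C2H5NO2	
alanine	amine	C3H7NO2	
serine	amine	C3H7NO3	
threonine	amine	C4H9NO3	
valine	amine	C5H11NO2	
leucine	amine	C6H13NO2	Leu/Ile
isoleucine	amine	C6H13NO2	Leu/Ile
phenylalanine	amine	C9H11NO2	
tyrosine	amine	C9H11NO3	
tryptophan	amine	C11H12N2O2	
methionine	amine	C5H11NO2S	
taurine	amine	C2H7NO3S	
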