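name	block_class	formula
glycolic	hydroxy_acid	C2H4O3
lactic	hydroxy_acid	C3H6O3
2-hydroxybutyric	hydroxy_acid	C4H8O3
3-hydroxybutyric	hydroxy_acid	C4H8O3
3-hydroxyvaleric	hydroxy_acid	C5H10O3
malic	hydroxy_acid	C4H6O5
mandelic	hydroxy_acid	C8H8O3
2-hydroxyoctanoic	hydroxy_acid	C8H16O3
3-hydroxydecanoic	hydroxy_acid	C10H20O3
3-hydroxydodecanoic	hydroxy_acid	C12H24O3
3-hydroxymyristic	hydroxy_acid	C14H28O3
2-hydroxypalmitic	hydroxy_acid	C16H32O3
10-hydroxystearic	hydroxy_acid	C18H36O3
12-hydroxystearic	hydroxy_acid	C18H36O3
ricinoleic	hydroxy_acid	C18H34O3
2-hydroxyoleic	hydroxy_acid	C18H34O3
15-hydroxyeicosanoic	hydroxy_acid	C20H40O3
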