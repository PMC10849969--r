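name	block_class	formula
acetic	fatty_acyl	C2H4O2
propionic	fatty_acyl	C3H6O2
butyric	fatty_acyl	C4H8O2
valeric	fatty_acyl	C5H10O2
caproic	fatty_acyl	C6H12O2
enanthic	fatty_acyl	C7H14O2
caprylic	fatty_acyl	C8H16O2
pelargonic	fatty_acyl	C9H18O2
capric	fatty_acyl	C10H20O2
undecanoic	fatty_acyl	C11H22O2
lauric	fatty_acyl	C12H24O2
tridecanoic	fatty_acyl	C13H26O2
myristic	fatty_acyl	C14H28O2
pentadecanoic	fatty_acyl	C15H30O2
palmitic	fatty_acyl	C16H32O2
margaric	fatty_acyl	C17H34O2
stearic	fatty_acyl	C18H36O2
nonadecanoic	fatty_acyl	C19H38O2
arachidic	fatty_acyl	C20H40O2
heneicosanoic	fatty_acyl	C21H42O2
behenic	fatty_acyl	C22H44O2
tricosanoic	fatty_acyl	C23H46O2
lignoceric	fatty_acyl	C24H48O2
pentacosanoic	fatty_acyl	C25H50O2
cerotic	fatty_acyl	C26H52O2
caproleic	fatty_acyl	C10H18O2
lauroleic	fatty_acyl	C12H22O2
myristoleic	fatty_acyl	C14H26O2
palmitoleic	fatty_acyl	C16H30O2
heptadecenoic	fatty_acyl	C17H32O2
oleic	fatty_acyl	C18H34O2
nonadecenoic	fatty_acyl	C19H36O2
gondoic	fatty_acyl	C20H38O2
erucic	fatty_acyl	C22H42O2
nervonic	fatty_acyl	C24H46O2
linoleic	fatty_acyl	C18H32O2
eicosadienoic	fatty_acyl	C20H36O2
docosadienoic	fatty_acyl	C22H40O2
alpha-linolenic	fatty_acyl	C18H30O2
stearidonic	fatty_acyl	C18H28O2
arachidonic	fatty_acyl	C20H32O2
EPA	fatty_acyl	C20H30O2
DPA	fatty_acyl	C22H34O2
DHA	fatty_acyl	C22H32O2
montanic	fatty_acyl	C28H56O2
melissic	fatty_acyl	C30H60O2
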