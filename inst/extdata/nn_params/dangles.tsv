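pair	base	side	dG
CG	A	5p	-0.5
GC	A	5p	-0.2
GU	A	5p	-0.3
UG	A	5p	-0.3
AU	A	5p	-0.3
UA	A	5p	-0.3
CG	C	5p	-0.3
GC	C	5p	-0.3
GU	C	5p	-0.3
UG	C	5p	-0.1
AU	C	5p	-0.3
UA	C	5p	-0.1
CG	G	5p	-0.2
GC	G	5p	0
GU	G	5p	-0.4
UG	G	5p	-0.2
AU	G	5p	-0.4
UA	G	5p	-0.2
CG	U	5p	-0.1
GC	U	5p	0
GU	U	5p	-0.2
UG	U	5p	-0.2
AU	U	5p	-0.2
UA	U	5p	-0.2
CG	A	3p	-1.1
GC	A	3p	-1.7
GU	A	3p	-0.7
UG	A	3p	-0.8
AU	A	3p	-0.7
UA	A	3p	-0.8
CG	C	3p	-0.4
GC	C	3p	-0.8
GU	C	3p	-0.1
UG	C	3p	-0.5
AU	C	3p	-0.1
UA	C	3p	-0.5
CG	G	3p	-1.3
GC	G	3p	-1.7
GU	G	3p	-0.7
UG	G	3p	-0.8
AU	G	3p	-0.7
UA	G	3p	-0.8
CG	U	3p	-0.6
GC	U	3p	-1.2
GU	U	3p	-0.1
UG	U	3p	-0.6
AU	U	3p	-0.1
UA	U	3p	-0.6
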