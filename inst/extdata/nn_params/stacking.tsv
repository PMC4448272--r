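bp1	bp2	dG
AU	AU	-0.9
UA	AU	-1.3
GC	AU	-2.4
CG	AU	-2.1
GU	AU	-1.3
UG	AU	-1
AU	UA	-1.1
UA	UA	-0.9
GC	UA	-2.2
CG	UA	-2.1
GU	UA	-1.4
UG	UA	-0.6
AU	GC	-2.1
UA	GC	-2.1
GC	GC	-3.3
CG	GC	-2.4
GU	GC	-2.1
UG	GC	-1.4
AU	CG	-2.2
UA	CG	-2.4
GC	CG	-3.4
CG	CG	-3.3
GU	CG	-2.5
UG	CG	-1.5
AU	GU	-0.6
UA	GU	-1
GC	GU	-1.5
CG	GU	-1.4
GU	GU	-0.5
UG	GU	0.3
AU	UG	-1.4
UA	UG	-1.3
GC	UG	-2.5
CG	UG	-2.1
GU	UG	1.3
UG	UG	-0.5
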