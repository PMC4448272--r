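name	value
asym_penalty	0.6
ru_closure	0.7
ru_end	0.45
c_bulge	-0.9
sym_correction	0.43
long_loop_coeff	1.75
gas_constant_J	8.3144621
temperature_K	310.15
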