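scope	metric	tp	fp	tn	fn
global	pocpu	209660	67329	253860	12966
global	pocp	220307	188155	133034	2319
Streptomycetaceae	pocpu	93338	7110	1231	2974
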