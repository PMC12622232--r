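s1	p1	80.0	80	16	0	1	80	1	80	1e-40	150.0
s2	p1	80.0	80	16	0	1	80	1	80	1e-40	150.0
s3	p2	80.0	80	16	0	1	80	1	80	1e-40	150.0
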