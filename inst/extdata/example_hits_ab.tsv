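p1	s1	80.0	80	16	0	1	80	1	80	1e-40	150.0
p1	s2	80.0	80	16	0	1	80	1	80	1e-40	150.0
p2	s3	80.0	80	16	0	1	80	1	80	1e-40	150.0
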