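class	n_pairs
between_genera	321189
within_genus	222626
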