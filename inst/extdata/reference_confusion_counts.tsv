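compartment	tp	fn	fp	tn
whole_plasma	23	7	6	21
EV	18	12	8	19
EV_free	30	0	19	8
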