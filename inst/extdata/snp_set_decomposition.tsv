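dataset	htsnps	bssnps	shared	bulk_total
rice	137224	109445	1099516	1346185
maize	6549258	3195935	6828768	16573961
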