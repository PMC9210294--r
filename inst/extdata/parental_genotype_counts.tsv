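dataset	homozygous	heterozygous
rice	2011062	153000
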