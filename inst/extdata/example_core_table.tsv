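structure_id	chain	ranges	label
synthetic_minicore	A	5-40	minicoreA
synthetic_minicore	A	1-60	minicoreFull
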