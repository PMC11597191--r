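origin	locus	with_sequon	without_sequon
AL	IGK	67	93
AL	IGL	39	485
MM	IGK	62	533
MM	IGL	38	336
OAS	IGK	360785	3917640
OAS	IGL	271185	3498137
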