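strand	start	end
A	1	15
B	16	26
C	39	46
C'	47	55
C''	66	74
D	75	84
E	85	96
F	97	104
G	118	127
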