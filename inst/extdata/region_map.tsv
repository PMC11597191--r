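region	start	end
FR1	1	26
CDR1	27	38
FR2	39	55
CDR2	56	65
FR3	66	104
CDR3	105	117
FR4	118	127
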