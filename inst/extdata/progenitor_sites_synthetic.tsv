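gene	position
IGKV1-16	18
IGKV1-16	75
IGKV1-16	86
IGKV1-16	88
IGKV1-33	18
IGKV1-33	18
IGKV1-33	75
IGKV1-33	75
IGKV1-33	86
IGKV1-33	86
IGKV1-33	88
IGKV1-33	88
IGKV1-39	18
IGKV1-39	75
IGKV1-39	86
IGKV1-39	88
IGKV1-5	18
IGKV1-5	75
IGKV1-5	86
IGKV1-5	88
IGKV1D-16	18
IGKV1D-16	75
IGKV1D-16	86
IGKV1D-16	88
IGKV1D-33	18
IGKV1D-33	75
IGKV1D-33	86
IGKV1D-33	88
IGKV3-20	18
IGKV3-20	75
IGKV3-20	86
IGKV3-20	88
IGKV4-1	18
IGKV4-1	75
IGKV4-1	86
IGKV4-1	88
IGKV5-2	18
IGKV5-2	75
IGKV5-2	86
IGKV5-2	88
IGLV1-44	37
IGLV1-44	109
IGLV1-44	110
IGLV1-44	113
IGLV1-51	37
IGLV1-51	109
IGLV1-51	110
IGLV1-51	113
IGLV2-14	37
IGLV2-14	109
IGLV2-14	110
IGLV2-14	113
IGLV3-1	37
IGLV3-1	109
IGLV3-1	110
IGLV3-1	113
IGLV3-19	37
IGLV3-19	109
IGLV3-19	110
IGLV3-19	113
IGLV3-22	37
IGLV3-22	109
IGLV3-22	110
IGLV3-22	113
IGLV5-37	37
IGLV5-37	109
IGLV5-37	110
IGLV5-37	113
IGLV6-57	37
IGLV6-57	109
IGLV6-57	110
IGLV6-57	113
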