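cohort	age_range	dataset	n	mmse_mean	mmse_sd
YA	20-34	1	26	29.48	0.77
ME	35-49	1	29	29.45	0.95
ML	50-64	1	34	29.56	0.66
OE	65-79	1	32	28.91	1.30
OL	80-93	1	16	28.44	1.41
YA	20-34	2	62	28.66	1.19
ME	35-49	2	49	28.77	1.12
ML	50-64	2	43	28.42	1.14
OE	65-79	2	38	27.84	1.22
OL	80-93	2	30	27.43	1.10
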