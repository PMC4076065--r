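pleiotropy	enzyme	locus	pi_pct	dn_pct	ds_pct	dn_ds	lrt
higher	4CL	Glyma17g07190	0.18	0.14	0.30	0.48	0.00
higher	4CL	Glyma13g44950	0.40	0.39	0.40	0.96	28.98
higher	4CL	Glyma11g01240	0.09	0.12	0.00	0.12e-2/0	66.60
higher	CHS	Glyma05g28610	0.17	0.18	0.12	1.49	112.46
higher	CHS	Glyma01g43880	0.03	0.04	0.00	0.04e-2/0	0.00
higher	CHS	Glyma11g01350	0.07	0.00	0.29	0.00	0.00
higher	CHI	Glyma10g43850	0.00	0.00	0.00	0/0	0.00
higher	CHI	Glyma20g38580	0.40	0.23	0.97	0.24	60.41
higher	CHI	Glyma06g14820	0.00	0.00	0.00	0/0	0.00
higher	CHI	Glyma13g33730	0.79	0.58	1.49	0.39	0.40
lower	CHR	Glyma02g47750	0.27	0.00	1.29	0.00	0.00
lower	CHR	Glyma14g00870	0.11	0.07	0.25	0.30	0.00
lower	IFS	Glyma07g32330	0.22	0.12	0.56	0.21	0.00
lower	IFS	Glyma13g24200	0.17	0.12	0.32	0.38	0.00
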