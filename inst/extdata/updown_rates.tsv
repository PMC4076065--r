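position	enzyme	locus	pi_pct	dn_pct	ds_pct	dn_ds	lrt
upstream	PAL	Glyma19g36620	0.16	0.01	0.63	0.02	0.00
upstream	PAL	Glyma03g33890	0.03	0.02	0.08	0.28	0.00
upstream	PAL	Glyma10g06600	0.07	0.00	0.30	0.00	0.00
upstream	C4H	Glyma14g38580	0.09	0.00	0.41	0.00	0.00
upstream	C4H	Glyma02g40290	0.00	0.00	0.00	0/0	0.00
downstream	IOMT	Glyma13g24210	0.22	0.18	0.35	0.51	0.00
downstream	IOMT	Glyma18g50290	0.44	0.37	0.68	0.54	0.00
downstream	IFR	Glyma01g37840	0.20	0.26	0.00	0.26e-2/0	1.13
downstream	IFR	Glyma04g01380	0.27	0.35	0.00	0.35e-2/0	25.15
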