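family	chrom_a	chrom_b	n_anchors	ks_mean	ks_sd	reported_mya
PAL	Chr 3	Chr 19	10	0.17	0.04	14
PAL	Chr 10	Chr 13	10	0.14	0.03	11
PAL	Chr 3	Chr 10	5	0.60	0.15	49
PAL	Chr 3	Chr 13	5	0.62	0.25	51
PAL	Chr 19	Chr 10	4	0.58	0.05	48
PAL	Chr 19	Chr 13	4	0.66	0.22	54
PAL	Chr 10-2	Chr 20	10	0.12	0.02	10
C4H	Chr 2	Chr 14	10	0.14	0.02	11
C4H	Chr 10	Chr 20	10	0.15	0.03	12
4CL	Chr 17	Chr 13	10	0.16	0.08	13
4CL	Chr 13-2	Chr 15	10	0.12	0.04	10
4CL	Chr 1	Chr 11	4	0.10	0.04	8
CHS	Chr 8	Chr 5	10	0.14	0.05	11
CHS	Chr 1	Chr 2	8	0.17	0.07	14
CHS	Chr 1-2	Chr 11	10	0.10	0.01	8
CHR	Chr 14	Chr 2	10	0.12	0.04	10
CHI	Chr 10	Chr 20	10	0.18	0.13	15
CHI	Chr 4	Chr 6	10	0.17	0.05	14
CHI	Chr 13	Chr 15	7	0.21	0.10	17
IFS	Chr 7	Chr 13	10	0.18	0.11	15
IOMT	Chr 18	Chr 8	10	0.22	0.11	18
IOMT	Chr 10	Chr 20	10	0.14	0.03	11
IFR	Chr 1	Chr 11	10	0.18	0.13	15
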