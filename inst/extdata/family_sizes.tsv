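family	Gmax	Pvulgaris	Mtruncatula	Carietinum	Athaliana	Vvinifera	Osativa	reported_average	legumes	dicots	dicot_monocot
PAL	8	6	6	5	4	11	9	7	4	1	1
C4H	4	3	2	3	1	2	4	3	3	2	2
4CL	9	5	4	6	6	4	7	6	5	4	3
CHS	13	11	21	4	4	14	15	12	4	3	2
CHI	8	7	9	5	5	3	4	6	5	3	3
CHR	2	2	4	6	0	0	0	4	1	0	0
IFS	2	3	3	2	0	0	0	3	1	0	0
IOMT	17	6	12	4	0	0	0	10	3	0	0
IFR	8	7	4	6	0	0	0	6	5	0	0
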