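# Published tetrad counts near the CAN1 HIS3 reporter cassette, one row per
# strain x marker interval.  kb is the physical interval length counting
# homologous sequence only (heterologous insertions cannot recombine).
# The GRY3630 natMX-MAT row's printed percent-recombination and kb cells are
# internally inconsistent with its counts (likely column garbling in the
# source table); its counts and map distance are reliable.
strain	interval	PD	NPD	TT	kb
GRY3629	natMX-MAT	269	0	16	9.7
GRY3629	MAT-kanMX	140	1	144	22.5
GRY3262	natMX-MAT	243	0	8	9.7
GRY3262	natMX-HIS3	245	0	7	7.8
GRY3262	HIS3-MAT	252	0	3	1.85
GRY3276	natMX-MAT	199	0	9	9.7
GRY3276	natMX-HIS3	203	0	7	7.8
GRY3276	HIS3-MAT	211	0	1	1.85
GRY3263	natMX-MAT	227	0	20	12.3
GRY3263	natMX-HIS3	233	0	12	10.4
GRY3263	HIS3-MAT	240	0	6	1.85
GRY3630	natMX-MAT	296	0	14	NA
GRY3630	MAT-HIS3	246	0	61	11
GRY3630	HIS3-kanMX	224	0	79	14.5
GRY3630	MAT-kanMX	167	2	139	25.1
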