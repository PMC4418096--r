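sno	name	length	mature	precursor	n_tpm_values	tpm_values	mature_start	mature_flag	mature_in_precursor	precursor_id	arm	arm_flag
1	ast-Novel-1-3p	20	AGTCATTAATGATATTAGAC	AUUUAUGGGAAAUAAUCUCUUUAAUCAGGCUUUAUAGUCAUUAAUGAUAUUAGACUGCAAUUCUAAAGGAAUAAUUUAAUUUAUUAAGGCUUAAGAAUUAAAAGAUUAAUACAAAUAUUUUCA	6	0.37,0,0.06,0.05,0.08,0	36	printed	AGUCAUUAAUGAUAUUAGAC	1	5p	arm_flipped
2	ast-Novel-1-5p	21	ATAATTTAATTTATTAAGGCT	AUUUAUGGGAAAUAAUCUCUUUAAUCAGGCUUUAUAGUCAUUAAUGAUAUUAGACUGCAAUUCUAAAGGAAUAAUUUAAUUUAUUAAGGCUUAAGAAUUAAAAGAUUAAUACAAAUAUUUUCA	4	0.18,0.16,2.84,0.18	71	printed	AUAAUUUAAUUUAUUAAGGCU	1	3p	arm_flipped
3	ast-Novel-2-3p	23	GTATTCAATTTGTATATCGTCGT	GUUGGACCUUACUUAAAUUUGUAUUCAAUUUGUAUAUCGUCGUCAUCAGAAUAUAUUAUAAGAUUAAUAAUUUUCUAAAUAUUUUAUUAAAUAAUAUGUCAGGUCAAGGUGCAGUUUAUGUUUAAGUAG	3	0.18,0.1,0.08	21	printed	GUAUUCAAUUUGUAUAUCGUCGU	2	5p	arm_flipped
4	ast-Novel-2-5p	19	ATTGATAATCCACGTTGGA	GUUGGACCUUACUUAAAUUUGUAUUCAAUUUGUAUAUCGUCGUCAUCAGAAUAUAUUAUAAGAUUAAUAAUUUUCUAAAUAUUUUAUUAAAUAAUAUGUCAGGUCAAGGUGCAGUUUAUGUUUAAGUAG	4	0.37,0.54,0.16,0.11		position_unresolved		2		position_unresolved
5	ast-Novel-3-3p	24	TTAAGATTGGTATGATTAGCGTCT	UUUCCUUUAAGAUUGGUAUGAUUAGCGUCUUGUUUAGCAGAAACUAAUCGUACUCCUUUU	3	0.16,0.12,0.24	7	printed	UUAAGAUUGGUAUGAUUAGCGUCU	3	5p	arm_flipped
6	ast-Novel-3-5p	24	AAACTAATCGTACTCCTTTTGATT	UUUCCUUUAAGAUUGGUAUGAUUAGCGUCUUGUUUAGCAGAAACUAAUCGUACUCCUUUU	1	0.16	41	truncated	AAACUAAUCGUACUCCUUUU	3	3p	arm_flipped
7	ast-Novel-4-3p	18	AATGGGTAGTCGAAGATT	AAUUGCUCAUGGUUUAUGUUCAUCUGGAUUAUUUUGUUUAGCUAAUAUUUCUUACGAACGAAUGGGUAGUCGAAGAUUAUUAAUUAAUAA	3	6,0.47,0.16	61	printed	AAUGGGUAGUCGAAGAUU	4	3p	printed
8	ast-Novel-4-5p	22	AATTGCTCATGGTTTATGTTCA	AAUUGCUCAUGGUUUAUGUUCAUCUGGAUUAUUUUGUUUAGCUAAUAUUUCUUACGAACGAAUGGGUAGUCGAAGAUUAUUAAUUAAUAA	1	0.3	1	printed	AAUUGCUCAUGGUUUAUGUUCA	4	5p	printed
9	ast-Novel-5-3p	21	CGTAGTTTCTACATTAGGAGT	UUUUACUUUUUUUGUAGGAUCAAUAUGAUUUAUACCCGUAGUUUCUACAUUAGGAGUAAU	3	0.12,0.1,0.04	37	printed	CGUAGUUUCUACAUUAGGAGU	5	3p	printed
10	ast-Novel-5-5p	21	ACTTTTTTTGTAGGATCAATA	UUUUACUUUUUUUGUAGGAUCAAUAUGAUUUAUACCCGUAGUUUCUACAUUAGGAGUAAU	4	0.6,0.42,0.56,0.18	5	printed	ACUUUUUUUGUAGGAUCAAUA	5	5p	printed
11	ast-Novel-6-3p	25	TTTCGGATATGAATCAAAGTAATTT	ACCACUUAAAUUUCGGAUAUGAAUCAAAGUAAUUUUCAUCAAUUCCCUCUACCCUCAUGAGCGAGUGAUGUAAUGUACUCUCGUUCUGGACGAUUUUCAACCACUUAAAU	6	100.76,44.78,95.03,141.73,135.2,796.74	11	printed	UUUCGGAUAUGAAUCAAAGUAAUUU	6	5p	arm_flipped
12	ast-Novel-6-5p	21	CGTTCTGGACGATTTTCAACC	ACCACUUAAAUUUCGGAUAUGAAUCAAAGUAAUUUUCAUCAAUUCCCUCUACCCUCAUGAGCGAGUGAUGUAAUGUACUCUCGUUCUGGACGAUUUUCAACCACUUAAAU	2	0.37,0.6	82	printed	CGUUCUGGACGAUUUUCAACC	6	3p	arm_flipped
13	ast-Novel-7-3p	23	AGCCGAACCAGCAGTACGAGTTT	GACCCGACCGAGCCGAACCAGCAGUACGAGUUUUAACGCACGUUUCUUCGACUGGGAGCGUGGCGUCUCCUGUAACGCGGCUACUCGUGG	1	0.04	11	printed	AGCCGAACCAGCAGUACGAGUUU	7	5p	arm_flipped
14	ast-Novel-7-5p	22	CGTCTCCTGTAACGCGGCTACT	GACCCGACCGAGCCGAACCAGCAGUACGAGUUUUAACGCACGUUUCUUCGACUGGGAGCGUGGCGUCUCCUGUAACGCGGCUACUCGUGG	5	0.28,0.3,0.31,0.04,0.18	64	printed	CGUCUCCUGUAACGCGGCUACU	7	3p	arm_flipped
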