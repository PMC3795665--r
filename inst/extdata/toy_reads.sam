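@HD	VN:1.6	SO:unsorted
@SQ	SN:toy_repeat	LN:120
r1	0	toy_repeat	1	60	40M	*	0	0	CGGTGCGCCTTGTTCGTGCTGTTCGGCTCGATGCCGCTCT	*
r2	0	toy_repeat	31	60	40M	*	0	0	ATGCCGCTCTGTTAGCTAGAATAACTAGAGCTTATCGTCC	*
r3	0	toy_repeat	51	60	40M	*	0	0	ATAAATAGAGCTTAACGTCCCTGTAGATCGAATTCGTTTC	*
r4	0	toy_repeat	71	60	20M5D20M	*	0	0	CTGTCGATCGAATTCGTTTCATCTGAATCTCTTAGATGTG	*
r5	0	toy_repeat	11	60	20M5I15M	*	0	0	TGTTCGTGCTGTTCGGCTCGACGTAATGCCGCTCTGTTAG	*
r6	0	toy_repeat	41	60	5S35M	*	0	0	TTTTTGTTAGCTAGAATAACTAGAGCTTATCGTCCCTGTC	*
r7	4	*	0	0	*	*	0	0	GTTCACATAGACTCGTTATCTTACGCAGCAGGGCGTCCTA	*
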