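@HD	VN:1.6	SO:coordinate
@SQ	SN:chrT	LN:600
@PG	ID:circjudge	PN:circjudge
L3	97	chrT	21	60	100M	=	321	400	GGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAAC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
L1	99	chrT	41	60	100M	=	91	150	GGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
L1	147	chrT	91	60	100M	=	41	-150	ATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
S1	2145	chrT	101	30	50M50S	=	91	0	CTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGCAACAAGTCGCACACACACACACACACACACACACACACACACACACACACACACACACAC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
J1	2145	chrT	201	50	60S40M	=	230	171	AGAGCACTCCAGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTCATGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCT	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
J2	2145	chrT	201	60	50S50M	=	260	141	AGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTCATGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTTGAA	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
J3	2145	chrT	201	20	70S30M	=	240	161	GTCGCCCTTGAGAGCACTCCAGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTCATGACCCTCGTGCATCACAAAGCCTCAA	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
J1	145	chrT	230	60	100M	=	341	171	AGCCGGAGTCTAGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAGTCGTCGGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACACACT	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
J3	145	chrT	240	60	100M	=	331	161	TAGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAGTCGTCGGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTT	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
J2	145	chrT	260	60	100M	=	351	141	TAAATCGTGTGAATACGTGAGTCGTCGGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCAGGC	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
L2	99	chrT	301	60	100M	=	351	150	ATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGG	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
L3	145	chrT	321	60	100M	=	21	-400	GGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGGTTATCTATGCAGCTAATAT	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
J3	97	chrT	331	60	70M30S	=	240	-161	GTCGCCCTTGAGAGCACTCCAGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTCATGACCCTCGTGCATCACAAAGCCTCAA	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
J1	97	chrT	341	60	60M40S	=	230	-171	AGAGCACTCCAGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTCATGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCT	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
J2	97	chrT	351	40	50M50S	=	260	-141	AGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTCATGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTTGAA	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
L2	147	chrT	351	60	100M	=	301	-150	AGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGGTTATCTATGCAGCTAATATCCTTAGTAGTCGACCCCTGAGATGACCGGT	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
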