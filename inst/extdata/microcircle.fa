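>chrT
AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGA
ACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAAC
GTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCT
CCCGCTTGCCGTCTTCAAAGTCATGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCT
AGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAGTCGTCGGAAAGCAGTTGAAT
ATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCAGGCG
AGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGGTTATCTATGCAGCTAATAT
CCTTAGTAGTCGACCCCTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCT
CCTACAGACTCGTGCTACCGGACCATGCGACTCGAACATCAGATGGACAGACCTCGTAAT
AGCCGGGCCATGTAACACTGATGTCTCCGGGCAGCTCATGACGAGCACCAGACCCGAGAG
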