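>synthetic_bg_01
TCAGACTGTCAGGAAATCGGTCAGAAAACATAATTAGGTACTACACAAAACACGCAACTTCCTATAGGAGTAATCAAATA
AATGGGTCGACAGTAATTGA
>synthetic_bg_02
TCATCAATTCGCATACTATTCTTAAAGCTTACCTAAAAACCGGACTACTTTCTAATTATACATCCCACCTTATGAGAACA
AGTATCCTCGTTGGACTGAC
>synthetic_bg_03
TGACACAGCGTACCCTCTCGCTTCTCTTTATGACTTTGCCCAGCTTATGAATGAATACAGACGCCAGACGTTGATGTCTC
ACAAGTGTAGGGCCTGTAAG
>synthetic_bg_04
GCGTGCGAACCTGTTAAAGCTATTTGCCACTGCAGGTCGTTCCTGTGTACCAGTGAACAGATGAAAGGCTGGAATAGTTG
CTAGCGGTGCAGGGAACTAG
>synthetic_bg_05
GATGCCCACGGGTGCCACATGGACCCCTTAACCGAAGGCATCAGCGTTCATAGCCGATGCTGTTACAGACTTTCACCGGA
CGCCTACTTGGCGACGCTTT
>synthetic_bg_06
AGCATGTAGCGGCCATCCACGTTTGACTATTAAGGCCCCCGAGGCGAAAACCATTGCCGCGGGTAAGTCTATAGCCTATC
ACATTGTAAAGGCATACTAC
>synthetic_bg_07
CATTGCCGATCGGAATATGGTACAGTTACTTGAAGCGATAAAGAGCTTAGTGTAAACCATTTCTCGACACGGAATAACTT
TTGGGGAGTTCTCCTGATGC
>synthetic_bg_08
AATTGGTCAGTATCATCAGGCGCAATCCTAATCGCTATGGGCGGATTATAACTGTTGAGAGATTTACCGTGGGCGAAACA
CTTCGTGACTCACACGCGAA
>synthetic_bg_09
GTGTTTCTGCTCTCGAAGCTTCTCCTGCGCGATGTCACGTTGCAAAGGGGTCTAGTTGACCTTTGCGTCCGAGACTAAAC
GTACATAAGCGCTGGTCCTG
>synthetic_bg_10
CTTGGTTAGCCACGTAATCGCCTAGGTATTGCGTGGATTTCTAGCCAGCTCCGGGCCTTCAACGGTCTTCACATCCTTGG
TCTACCAAATTCAACTACTG
>synthetic_bg_11
TCGCCGGGGTCCTGCCCTAAACCACGCGCAGAAGTGGAAAAACTGCATCTGCTGCGCATGACTTTTCACTCATGGGTCCT
AGGAGCCCACCGATCTGTCA
>synthetic_bg_12
TGATACAGGCGCATTGCAGGCACCAAAAAATTTTTTTTCGCTAATATATCGCTCCGCAGGGTCAGTGTGATAGAAACCAT
AACCGTGACCTCTCAGTGCA
>synthetic_bg_13
GATACTTTTTCTTTGACATAATTTACCTAATTGATCGTAGCACTGGACCATAAACCCGGCAGCTTAACCCATCTCCGGTT
TTTGCTGTTCTAAAGCGGAG
>synthetic_bg_14
CGAGGAAGTGAGTCAGGGGTTCTACTTGTTTCAGCCACAGTCCAGACAGCGTCTAGAGTTTCAAACTTACACGTACACAC
GCACGAAGAGGTAAGGTCCC
>synthetic_bg_15
TGTGAGCACTGGTGTATTTCGGTGAGATTTATCCGTCTCTCGGAACTAATGTTATCAAATCCTCTTAGAGGTTAAGAATG
ACAACATCTGCAGATTCTTT
>synthetic_bg_16
ATGTCTCCTGATTGTATGGCCGGCCCAACCCTCTGGACAACCCATGGCGTAAGGGTATTTCGAATTATATAACTGTGGAT
GTCCCGATTCGCTGTCCGAT
>synthetic_bg_17
CTAGGCCATCGCACTTAAAGGAGCGAGTATCTCCCCGTCCCACTCACTTCTAATTGGTCGAACCAGTTCTGTCAGGGCAG
GCTTTCCGCCCTAGTGGTGC
>synthetic_bg_18
GCCATTTTAGAACCTAGCTCTAGCTATATTGACAGGCGAGCTCCCTCTGACTTAAGACGGTGTCCGGTCTGTCCAGTTCA
GGTCTACACAATCAAACACC
>synthetic_bg_19
CTCCAAGCTCCATCCTGCCTAAAATGGTACCACTCGCCCCTCTCCGCAAACTTCTTGATTAGCTTTCCAGTTCTCACTTA
CCAACCTATGAACTAGAGCC
>synthetic_bg_20
AAACCATTAATCCCAGACGTCTGATGTCCATTGTGGCTTAGGTTTAGTGCAGACGCGATCGTTATAGTAATAACGAATCC
TGTTTAGCACTAAAGACCAC
>synthetic_bg_21
TCCACTTTGCTAGAGAATATCGTCGAGTTGGTTTTTTATTGATGCGCATCGGAGAACGTCATCGAGCAAGGAAGCGCATC
ACGACCTGCGCTACCCGTTA
>synthetic_bg_22
CTACCCAGAAATCGGCAAGTTGATCTGGCATAGTGTAGACTAAACGTAACATATGCGCTTTCTCGCTACCTTTGGACGAG
AATCTGTTTTTAACTGTTGC
>synthetic_bg_23
CCGGGTAGTTGCAGGCTAAAACGTCGACATACTCCCCAACTCCTCTACAAAGAGCTGGTCCGTCCGACAAAGCAGAGGCG
CGCCTCCAGAACCGTGGCAC
>synthetic_bg_24
TTCTGTGTGCCCGACCAGAACTACCGAAGCGGCTATGTGAGTTGCCATCTCTGCCAAGTTGCTATGCATTCCACAACTTT
GGTTCCCCGTCAGCGTCGTG
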