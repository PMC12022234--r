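>w22|wolf
CCTCAAGCTGGGTTTACGTTTTGTCTGCAAGGTCCGCATTGCCATCGCCTTGCGCACCGC
GCTCATCACACGCGCGGATATGTGAAACCTTGCACTTACGTCGATAAGTCTGCCAAAACT
CTATCGACGAATAGACTTAAGGTATGTTACCGAAGCGTGCAATCATATATGTGTGACTCC
TTGAAGTTGTGGTTTCCCAAAGCTATATTTGTCAATCCACGCTCAGGACGCGACTAGGTA
TGTACATGCGACGATATACAGGAGCCGTCGCGAGTCCCCTCCGACTTCCCGTGCTTTGGG
CCTCAATCGCAAACTGCCAGCAAACGACGCAATCGATGCGAGCGGGTCTCGTATGCGGGC
AGTGATGTTACAGCTCCTACCTCCTTATTGGCTAGTTTAAGCCACCCGTACGCGCGCATC
GCGAGCATACGCTTTTTTAGGACAAATGTCTCCGTTGTTCAATAACATAACATAAAGTTC
CCATGCATTGTCCTCTCCCATGCAAACCCAAATGGACTGACCAGAGTCAGCTAACATCCG
TCATCTTCTTGTTAAGTCGCCCTCTTGAAACTACTTCGTGGATGGTTCGAAGTGAACTTT
TGGTG
>w1|wolf
CCTCAAGCTGGGTTTACGTTTTGTCTGCAAGGTCCGCATTGCCATCGCCTTGCGCACCGC
GCTCATCACACGCGCGGATATGTGAAACCTTGCACTTACGTCGATAAGTCCGCCAAAACT
CTATCGACGAATAGACTTAAGGTATGTTACCCAAGCGTGCAATCATATATGTGTGACTCC
TTGAAGTTGTGGTTTCCCAAAGCTATATTTGTCAATCCACGCTCAGGACGCGACTAGGTA
TGTACATGCGACGATATATAGGAGCCGTCGCGAGTCCCCTCCGACTTCCCGTGCTTTGGG
CCTCAATCGCAAACTGCCAGCAAACGACGCAATCGATGCGAGCGGGTCTCGTATGCGGGC
AGTGATGTTACAGCTCCTACCTCCTTATTGGCTAGTTTAAGCCACCCGTACTCCCGCATC
GCGAGCATACGCTTTTTTAGGACAAATGTCTCCGTTGTTCAATAACATAACATAAAGTTC
CCATGCATTGTCCTCTCCCATGCAAACCCAATTGGACTGACAAGAGCCAGCTAACATCCG
TCATCTTCTTGTTAAGTCGCCCTCTTGAAACTACTTCGTGGATGGTTCGAAGTGAACTTT
TGGTG
>w2|shared
CCTTAAGCTGGGTTTACGTTTTGTCTGCAAGGTCCGCATTGCCATCGCCTTGCGCACCGC
GCTCATCACACGCGCGGATATGTGAAACCTTGCATTTTCGTCGATAAGTCTGCCAAAACT
CTATCGACGAAAAGACTTAAGGTATGTTACCGAAGCGTGCAATCATATATGTGTGACTCC
TTGAAGTTGTGGTTTCCCAAAGCTATATTTGTCAATCCACGCTCAGGACGCGCCTAGGTA
TGTAAATGCGGCGATATACAGGAGCCGTCGCGAGTCCCCTCCGACTTCCCGTGCTTTGGG
CCTCAATCGCAAACTGCCAGCAAACGACGCTATCGATGCGACCGGGGCTCGTATGCGGGC
AGTGATGTTACAGCTCCTACCTCCTTATTGGCTAGTTTAAGCCACCCGTACGCGCGCATC
GCGAGCATACGCTTTTTTAGGACAAATGTCTTCGTTGTTCAATAACATAACATAAAGTTC
CCATGCAATGTCCTCTCCCATGCAAACCCAAATGGACTGACCAGAGTCAGCTAACATCCG
TCATCTTCTTGTTAAGTCACCCTCTTAAAACTACTTCGTGGATGGTTCGGAGTGAACTTT
TGGTG
>w7|shared
CCTCAAGCTGGGTTTACGTTTTGTCTGCAAGGTCCGCATTGCCATCGCCTTGCGCACCGC
GCTCATCACACGCGAGGATATGTGAAACCTTGCACTTACGTCGATAAGTCTGCCAAAACT
CTATCGACGAATAGACTTAAGGTATGTTACCGAAGCGAGCAATCATATATGTGTCACTCC
TTGAAGTTGTGGTTTCCCAACGCTATATTTGTCAATCCACGCTCAGGACGCGACTAGGTA
TGTACATGCGACAATATACAGGAGCCGTCGCGAGTCCCCTCCGACTTCCCGTGCTTTGGG
CCTCAATCGCAAACTGCCAGCAAACGACGCAATCGATGCGAGCGGGTCTCGTATGCGGGC
AGTGATGTTACAGCTGCTACCTCCTTATTGGCTAGTTTAAGCCACCCGTACGCGCGCATC
GCGAGCATACGCTTTTTTAGGATGAATGGCACCGTTGTTCAATAACATCACATAAAGTTC
GCATGCATTGTCCTCTCCTATGCAATCCCAAATTGACTGACCAGAGTCAGCTAACATCCG
TCATCTTCTTGTTAAGTCGCCCTCATGAAAATACTTCGTGGATGGTTCGAAGTGGACTTT
TGGTG
>w14|shared
CCTCAAGCTCGGTTTACGTTTTGTCTGCAAGGTCCGCATTGCCATCGCCTTGCGCACCGC
GCTCATCACACGGGCGGATATGTGAAACCTTGAACATACGTCGATAAGTCTCCCAAAACT
CTATCGACGTATAGGCTTAAGGTATGTTACCGAAGCGTGCAATAATATATGTGTGAATCC
TTGAAGTTGTGGTTTCCCAAAGCTATATTTGTCAATCCACGCTCAGGACGCGACTAGGTA
TGTACATGCGACGATATACAGGAGCCGTCGCGAGTCCCCTCCGACTTCCCGTGCTTTGGG
CCTCAATCGCAAACTCCCAGCAAACGACGTTATCGATGCGAGCGGGTCTCGTATGCGGGC
AGTGATGTTACAGCTACTGCATCCTTATTGGCTAGTTTAAGCCACCCGTACGCGCGCAGC
GCGATCATACGCTTTTTTAGGACAAATGTCTCCGTTGTTCAATAACATAACATAAAGTTC
CCATGCATTGTCCTCTCCCATGCAAACCCAAATGGACTGACCAGAGTCAGCTAACATACG
TCATCTTCTTGTTAAGTCGCCCTTTTGAAACTACTTCGTGGATGGTTCTAAGTGAACTTT
TGGTG
>fox1|other
CCTAAAGCTGGGTTTACGTTTTGTCTGTACGGCGCGCATTGCCATCGCCTGGCGCACCGC
GCTCATCACACGCGAGGAAATGTGAAACCTTGCACTTACGTCGAGAAGTCTCCCAATACT
CTCTCGACTAATAAACTTAAGGTATGTTATTGTAGCGTGCAACTAAATATGTGGGTCTCT
TTGATGTTGTGGTTGCCCAAAGGTATATTTGTCAATGCACGTTCAGGACACGACTAGGTA
TGGACATGCGACGATATACAGGAGCCGTCGGGAGTCCACTCCGAATTCCCGTGCTTTGGG
CCTCAATAGCAAACTGCCAGCAAAGGACGCCATCCATGCGAGCGGGTCTCGTATGCGGGC
AGTGACGTTACAGCTCCTACCTTCTTATTGACTAGGTTAAGCCACCCGTACGCGCGCATC
GCGAACCTACGCAATTTTAGGACAAATGTCTCCGTTGTTCAATAACATAAAATAAGATTC
CCATGCATTGTCCTCTCCCATGAAAACCCCAATGTACTGACCAGAGTCCGCTAACATCCG
TCATCATCTTGGAAAGCCGCCCTCTTGATACTACTTCGTGGACGGTTCGAAGTGAACATT
TGGAG
>dog1|other
CCTCAAGCTGAGTTTACGTTTTGTCTGTAAGGTCCGCATAGCCATCGCCTTGCGCACCGC
GCTCATCACACGCGCGGATATGTGAAACCTTGCTCTTACGTCGATAAGTCTGCCAAAACT
CTATCGACGAATAGACGTAAGGTATGTTACCGAAGCGTGCAGTCATATATGGGGGACTCC
TTGAAGTTGTGGTTTCCCAAAGCTATATTTGTGAAACCCCGCTCAGGATGCTACTAGGTA
GGTACATCCGACCCTATACAGGAGCCGTCGCGAGTCCCCTCCGGCTTACCCTGCATTGGG
CCTCAATTGCATACTGGCAGCAAACGACGCAATCGATTCGAGCGGGTCTCGTATGCGGGC
AGTGATACTACAGCTCCTACCTCATTATTGGCTAGTTTAAGCCACCCGTACGCGCGCATA
GCGGGCATACGCTTTTTTAGGACAAATGTCTACGTTATTCTATAACATGACCGAAAGTTT
CCATGCATTGTCCTCTACCATGCAAACCCAAATGGACTGACCAGAGTCAGCTAACATCCG
TCATCTTCTTGTTAAGTCGCCCTCTTCAAACTACTTCGTGGATGGTTCGAATTGAACTTT
TGGTG
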