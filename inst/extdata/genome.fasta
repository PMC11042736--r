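>chrS
TAAGACGTTTTACTTACTGCTACGTCAATCTAACGAGCCTACCCCGACAGACTCGGATTGCACAATTTTAACATTGAAAA
CGTCTGCCCGGCTCGGCTTAGTGCTTGAATTGTTTGACCTAAGCACGCTTAGAAGTTAGTTTTGTCCCTACCAGCGGAAA
ACTAAGCAATCGTTACTTCCGCGCGCCCTTAAGTTTTTTCGGTCCTCGGCGCCAATCTACCCTACCAACCTTCTGGAATA
ACCCTTTCCGAACCGGGTGCTTGCAGTTCAGCTCAATGGTATTCCGCACTAAAGGGGTCGTATTCACGATACTGTTACTT
TCAATACACGTGAACTCGATTAATTGCCCATGACCTCCGGGGAGTCCAGGGATCCCGGCATCTTAAGAACTGAACATACT
CCTCGCCAGACGGCGGCGCCTGTAACTTTAACCCTCTTGGGTAATGCTAGCATTGGGGTCTACTGACGGGTATGAAAAGG
GGCGAGACTGAATAGCAGTTGTCCCGGTCTTATTCAGCAATGTGGGGAAACCATTTACCACAACGGCGCAATAGCTTTGT
CTGGAGTCTTCAGTTCGAGCTAGCATACCCCTTTGGCGGGGCGAATGCTTCACGGATCAACCTCTTCATGGTTGGTAGAA
CGAGGTAAAATAACACGATTACCTTGAGGTGCGAGATCCTTCAGACCCCAAGGCCAAAGTTTAGTAAACATAGGGGTTTC
AAACTTGGTATATACGTATAGTAGATATAAGACGAGGATGCAATGGGGGGACACCAGTCAAGACTCAAGCGTTTGAAAAA
TCATGTGGCGCGACAGTCGAGCCTTGTTCTCACGTGTTAACTCGTCGTATAGTACGACCTAATTGCGGAAGTACCTGCGT
GAGAAGCACAATCATACAGCGAGTATGGGTATGCGGAGCTACGAATGTCTGACAACAGTAATCCTAGCGGTTAGTACTCA
CGTACCCCTAATCTAGAATAGGAACACTGGGCAAACGCTTACACAGTAGAGGTTAAAGCCTTCATCGACGTAAACTGATG
GAGCTCTGATAGCTGCCAAGGACTTATGCGATGCGAATGTAAGCCCGGTCAGTCTTCCCTATAAATAGGGTGACGACCTC
TAGAATTTGACTGAGTGCGGGGCCAGCCGGAGCGTACCTGAGTAATGAAGAACCGGACACCAGAGCTCCATTTGCCGAAA
CACTCCAAAGTCTGACTAACGGAAGAAAACGGTGAAATTAATACTCACAAATAACGGGCTATAAGTAAGGGCGGGCTCTG
AGTAACACCTGGTTGATCATTCGTCCGTGAGCAGAACGTCGGACGATGTGTAGTAAAAATAAGAAGGCAATCAGACCTGT
ACACTTACGGGCAGTCGGTGCTGGCTCTAGGACGATAGTCGTAGTTACACAATTCGTTTAGACCGTCTGCCGATTTTGAA
TTTATTTACCTTAAGGCGTTGTGTGAATCAGGGATGGAGCCATTGCCAACCAGACTGATAGCAATCTTGTCAGAGATTTA
ACCCCGGACTGCGATTTACAAATCAGGAAGTAATCGGTTTGTCATAACCTGTTTATATATAACCAAAGGTCGCTCGAACG
CGAGGGAATCATATCTGTGACAGGAATGCGACCGATGTACGCTCGTGCCTTGAAATTTAAAATCGTGCACGACTTCCTGA
GTAGGTGAGCATTGCGGCACATGCGTGCTACTATTGACAGGCCATTTGTTTTAAACTTATCGTCTTCCCCTTTTCTGAAC
CCGAAACTCGCCTATCCGATTGTTAACCCCGACACCACACCTAGCACTTGTTAAGATTGGGCTCTGCGACGAGAGAACCA
GGTGATCGGCCACTGACACAACCCAGCATAGACAGGTAGGGTGCTTCTAAGATGCTAGGACAAGAGGGGGTCATTACTAT
AAGGACAAACTACGTAGTCCAGTGATTGCGTCAAAGGTCGCCTGAAGGGACGAAACTTTGGGGGCTTGGCTTCTTCTATG
TGCGTGCATTATTAACAGGAGAATCTCTTTGTTTTTAGTCAACACTTCAGGATATCTCGTCGTGGCAGGTACAAGCCGAC
GATTGGTCGTAACAAAAATAATCCCCGAGCACCCAATTTAAGGTCGTACATTGGCGCTCGTTATAAATGGCTGTGGCGAC
ATTCTGCACTGGTATGGAAAACTTGTGATGCCACGTTAAAGAGAGTCCTATCCGACGGTCGGGTACTAAATAGGTCTCTC
CGGATTCAGAGACATTGACACGGGTTGGCCGGCAGCTCCGTTTACGGCTCACACTGCGAAGCAAGTTGCCGTCATAGACG
CAGTATGATAATTTTGCCCTTAGACTATCCGCTGCAACGCTGGATCGTAGGGAGGAACGGGGTGGCACAACTACGTTAAT
GTTATGGAACCATTCTTTAGACGGGTAAATAATTTTCTAGCGGCACCTACAAGAATACATTGGGCCTTGAAGTGCGGAGA
TACCCACCAGCGTCTTTTGGAGAGCATAGACGCATGGTAGTTAAATCACCAGTCTCACTAGATTACATGTTGACCGGCAC
GAAAGAAGTTCAAAAGCGTTACTCGTGTCTTTTGTCCCACTGCATGAGAACGAGACGGAGTCGTGAACGAATGGCAGCGC
ATATCGAGAGATGGTCCGATACGAATTACCGATTCTCTGTGGTTCTATACGTTACTCGTGAGGTGGCAATCTGTTTTAGT
ATGAGCCAACCTGTCATGCGGGTTCTGAAGATTGGCTGTTACTATCCAGTGCCAAGAACAAGTCGGCACAACTAGCATAC
GAGTTCGAAAACTTAATGCGTGCATTATTAACAGGAGAATCTCTTTGTTTTTAGTCAACACTTCAGGATATCTCGTCGTG
GCAGGTACAAGCACTCAAACTCACCGGCTCAAGGAGTTTGGGCAGCGGCGAGTTGCGTCAAGTTGATAGGTGAAAAGCTC
TGTTTAATAGCTCGCTGCAGATATAGGATAAAGCCCTATTGTAATCGCGCTTGAATGTGCGGGTGGGATCACATCCTGGG
CGTATCAGCGATGATGAGTCAGCAGGGCCATAATTTGAAAGAGGCAATCAAGGGCAATGACGGTGGGGTATGGAGGTCCG
GCAAGAGGCTTCTAGAAGTTCCTTAGCCGACTCCAGCGGAGCGGTCGCATCCCCTAACGATTTCCGTGTCAATGGCTTAT
GCATGTATGGGCGGCGCCACAGGGCGAGAATGGCTCCTAGCTCGACCCTGGCAGCCCTCAGAAGCACAAATCACTCATCG
TGACCCATAGGAGTTCATGATCTATGAATATTGGTACACACGGCATAAATTCATAACATCGGCTTCGACTCGAAAGGCTA
GCTAACACGAAAATAGTCTCCGTTTGCGTAGGAGCCTTAACTCCCAGACGGGAAGCCCTCATTTTCGCAACGCTTGCCTG
ACCAGCCCTTCTTTACTCAGGGTACTTAAGGCATATGACGCGGTTTGTCCAATCCGTATCAAGAGTCATCACGCGTGCTG
TAGGCATACTTAGTATGGATCACACATACACGACGTGAGCTTCATATACTGAAAGTGAAGGGCAATACACTGTTGACTTC
GACCTCGGAGAGTGCCTAATACCTCATCCCCTGGTTAGCCCTTAGGATCTGCAGTCATGTCTACCTGCGTAGGGTTCTTG
GAACACATGTCGCTATCTACTCGACAACGTTATTCATCTCCGGATTATTGCTACCAATATTTGTTAATATGCACACGCGA
TCGAGAACTTCTCAAAACACGATTAACGCGTTCAGCTCGGATCTTCATGGAGAACCCATTTTATTAATTTATAGGACGGC
ACTAGGGCCATCTCAAGGCGCATTATGAGTAGATGCCTTTCCTGTGACCAGGACTTAAACCAGTTCAGGCATTCGCCGCT
CTTTGCATTATCAAGTACGAGGCTCTGTATAAGGGGGCGATACAGGAATTAGTTATAGTGTTCCTCTAATAAGCCGCTTC
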