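>PC1
TAGCTCGATATTAGGGTAAAAACTGTACAATTTTATGCGCCTGCTCTTTAGCGCACATCTCAGGTCTCACAGTTTATAGG
TGATTAATACACATAACTTAACGAGGTTAATCACGTAAATTCTGTTGCAAATTCTGTTGTGCGAATGTACTAGCCGATTT
TGGTACCCCAGTTACATAGATATTCGCGAGTGTGTGGCGGATTTAGATAATTCGTAAAGTTCCATAATAGCGAGAATTAG
GGGTAGAGTCGATGCACCATGCTAGACCTATCCGGGATTAGACTGGGCATACTCGGAACGACAACTCAGAAATTGTCGCC
TGACCATAAAATGCGACAACCCATGAGTACGGAGCAGGGGAGATTCATAAACTGCCTACAGACGAGAGACAGGTAGTCAG
AGTAAAGTAAAATCAATAAATCATCAGTAGAGATCTACAAACCCTTCTCTGGTATAGTTAATTCCGCAAGAGTGGTTGCA
CAATTGTTATATAACTCCGT
>PC2
TTTTAAGTCTGAAACTTAGAATTCCGAAATGGTCAATCACACGTACAAAACCTAAAAACCTTCGTTGCGTGACCCATGCC
TGGAAAGAACAGCCTCCACCGCTTTTTTACTTCTGTGCATAGAACCTGGCTATTACAACATACGTAGATTATTTCAATGT
ACTCTGAACTAAGCTCTCTCGTGAATAGAACTCCGGTTAGTATAGGAAAAAACTTATAAAGCATAATTCTAGCATTATCA
CGAGAAACAACTGGTAATAAAAGGAAAGCTGATCGCCCCTCCCCAGCTTAATTAAAATTAGAGCTCCTTACTCGAAAAAG
GAGTTGTCTAAGCGCCTCTAGTCGTCATCTAGTCGTACCTTGATAATAAGTAAACGAAGAAAAGTACATATCGCTGGATG
AAAACGTTCTCTCGTAGATGAATCACATAACATTATTTTTCTTATTCGGTTCACACACATTGTGATCTCAAGAAACTATT
TTCACGGCTTGAATTAAATATCCACCTTAAACAGCGAAAGTGTGTTAAACCGCTACGTTTTCCTTCACATAAATATGGCA
TATTTACAAGTTGTATTCCTGTCGTAACAGAGTATTAACATCGTACTTTTGATCTGTCGTGTAATATACGAAATTATACG
GGACGTTACATGGCTATCCTAACATTTTCAAATATTCGAGATATACACAGGCAATACTATGAGCGACTGGTGCTAACGCT
TGCTAAGGAGTCCATCGAGGAAAGAGCTCATTCGAGTTAGCTAAATCTGTTAATCCTAATTACTCAGGATGGAGCGTTTT
>PC3
ATTTAATGCATTCTCTACCTCTGGGTAAAAAATATAAAATCGCACGTTTGACAATCATAACCTTGTATTTTTGTCAATTA
TGCATATAAGGATTAATTATATTGGTAAAACAGGGTCTTATGTAAATGTTGCTCAGTTATATGATCCCCATCCGAGAACA
ACTAGCTAAACACACCTTCTGTTCAATATGTCAACTTGACTCCAACGTTTACGGTTCTCTGGTATTAAACGCTGTCACAC
TTTTGCTTAACGTCTCCCCGGCTGCAGGTATTCTGAGACAGGCTGGGTGCGGGGGCACGC
>SHORT1
TGGTTGGCCTAGTTTCTGCAAAAAGATATAATCTAGCATCAATGGTCTCATCCGATTACCGCATCAAAAGCCGTTTAGTA
TCGTAAGACAAGTTATGCAGTACTTTCGGTTCGCCTTTCCTAGCAACGGGACATCTAGACTAGATCAACG
>MONO1
ATCCAATGACTATTGACATAACATCGGACAAAAACTCATACACGAAGTCTTTCTGTAGCTCGTATAAATGGGACCTTCAG
TCTTGTTTTATATAAGATATAGCACCGCTTGGAAGTCCCTATTTCAGGTCACGAAATACGTAAGTGATCTTCAGAATGGG
TCTCTTGGCTGCAACTTATTTCGGATTTCTAATTTAAAGTCAAGATATCTTTACCCTGATGAAAATAATTCTCAGCTATT
GTAATCCTTGGCCATCTATCAAAACAATCGTTTGTTGATTTCTAGTCACAACGCGGTTGAAGATTATTTTACTTCGAGTG
ATGCAAGCAAAGTGGATATGCACTTTTCACTTTTATAGACAAATGTGTGGTGGCCGGGAGTCGACCAATGTGTGAAGCCC
TTATACCTACGTCATCTCCGGGATACGGACGGCCCTAAAAAGGAAACTGTGTGCCGTCCATAGGTGTGCAAGGTGGATGA
CTCAGACGATTACTCCGTAC
>LOW1
AAAACGGCTGTAGGTTTAGTTGTTGTGAGTCTGACCACGTACGGAAGATTAATGTTTAGAATAGTATCGAATAATCCACT
TCACGAACAATCGATGATGTTATGCTTTCTTATTCAGACCAGTTGGAATTCAACCATTCAAGCGCCAAAAATTGTGTTAC
TTCGAGCCATTTCCGTGACGCATTCTTCATTCTTGTCGAGTTTCCTATCAGTCGAATTTATTCGGTAATTACTAGTTTTA
GTCTGACAGTTCAATAGCTAGGACCCAAACTAATAAGTTTTAGCTCACAAAACTACTACGGTGACCATACCCTCTAAGAA
GGCAAGGGTTAAAGAACGTCATAATACTTTTAGGTGGTTGAGGGAAACAAAGCAAATCGAGAAGACAAGAAGATGCATAT
ACTCCGTAGATTGTAGTACATTGAAGGTGCGATAAGCAATATGGTATTAACAAGTTTAACTACAGACATATACCTATAAA
GTCTTTTACATAAAATTTCT
>EDGE_LEN200
AGATGATATATTAATAGTAGAGTTCATGTTGGAACAATAGAAAGTTATATTCGCCGAATACTTGTTGACTGTAGTCCAAT
GTTCAACCACTAGGCCCTAGAAATCTATTAGATGTTCTCAGAGTTCATGATTTTACCAAGGCGCGCGCTCCTTATGATTA
GATAGAAAACTAATTTTATCGTTTCTTTCGCTCGTTCAGC
>EDGE_CNT10
GTCGACTAGATCCGGGTGGTTTGCTCGCGGAGGTTACCACTATCTATTACTATTTTAAACCTTTCGGTTGAATTCAGCTA
ATCCCATAACATCCTTGACATGTGAGGTCATTCGGTCTCCTTAACCTAACTCTATTACTGCTGGAGGCGGAAAATACCAC
GCTGCTATCTCCTAGACATCAGATGGTAATTCAGTCCTGTTATGGAACGAACTAACTTACAGAGAGTAAATCTTGACGGT
CAAAAATTTAAAGTAGCGACCTTGCGTTCTTTTGTAAAGTCGGACGACTTACAGAAATGTGGAGGAAATCGTGTAATATA
GTGGAATAAACCTTTTCTTACACCTGTAGCATATTGACCCTCACATTATAGGCTTGCGGTAGACGCATAGTATAGCACTT
ATAACTAACCTCTCGATCATTAAATGGATTATGCTGAGCTAGTCCGTGGCGTCATCAACATTGTCGAATCCTTGACCGTT
TTTGTCAGAAAAATCCGAAT
>KEEP1
CCGTTTTATAATGTCTCCCGTAGCCTCAAGTCGGCAATAGGACCAGGATAGTGGAAACCGAATATTTGACCTGTTTGTTC
TCTTTATAACGATCTTTTCTTACCAGGTTATATGCGGTGTTCCAGTTAAGGAGATTTTTCACATGATAAAACCTGGTGTC
AGAATAAATGTAGGCCACCAACCGCTTCGGTATACCCGGAT
>KEEP2
TTGCAAAATTGCTGAATTTGCAGAGCCAATGATAGTTCGAGTATAGCCATTGTTTACAGATAACACAAAATTAGCCACCT
GCACTTTCGTTTACATGTATTATAGCTATAGGAGCTTACGTATTCATCGAAAATGTAACCAATCAATCATAATGGATCGT
GTAGAACCTGGGTTTTGTGTTCACACTTAATTGTGAATTGGCGTGCTGTGCGATTTGACCCTTATCAACAATCAACTAGA
GAACCAAAGGTTGCTTTTATTTTAACGTATTCCTAGTCTCAGGAACGACTTTGCCTCATACTTATCTATTAAGAATCAAA
TTGGCACCTCCAAGTTTTATACGGAATATCAAACCTATTTAAACTTCTTTAAGCTCTAGTACATTCATCGTATAGAGAAA
CTGTCATTCTTTTCAACAACCTTCACCTAGGTAGCGGGTTAATAATGTCTCACTCAAGATATCGTAGCATGTCGTTAGAA
ACGATTTGGCGAAGGATTAA
>KEEP3
TGGCATCCTTACCAGTGGTCTTTCTACACGGTGAATAAACTGGTCTATTTAACAACGAGGAGGCAGGTATATACGGATTT
AATTTATTAAATTTAGAATTCCGGGTTTTGTCTAAAGGAAAGAATATATGATCCGAAGTGTGGTCCACTTTGTAGTTGCG
ATGGTATCCCATCCGGTCGCCAATTTAGCGGCGGTTTAAAATGGATGTCAAAATACAAACTAAGTTTCCCTCCTCCATCG
CGTGACCCTTTGGACCTCAATCGTACTTAAAATCTACTTAGGAATCTGCCTTCCTTGTAGTCAGTGCGCACATTTGGGCA
CCTAATTGCCGTTCGCCTAATACAGTTTAGTTAAGTCAGGGAATTTAATCGCGCAGAAGGATTTAAATTTTCGCCGCGAG
ACACGGCAGTCTAAGTACTAATACCCTGGGACGAAATCTAAGGACTCAAATGTTTTGTTAAGTTATTTGTCATAAGTATC
TCCATACTCACACACAAAGTGAGCCTAATATGTATAATTTGAATAGATATTACAGGATCCAATTCGAGATTAGTAAATAA
TCTCTCAGTCTATCATGATTGGCAATTAAAGCATTACGGTTAGGTGCTTAAGTAGGAACGAGGGTATGTGGTTCTGATAT
GTAATCTCGATGCAGCCAACTCTAGAACCACGCATCGCAAACGAATCTAACCACCTTCCA
>KEEP4
ATATTGCTCGGTTGAATTTTTAAGCTAATAGACTTCGTATTGAGAATCTCAGCAGGCCATATCAATCTTCAAGCGGTGGG
GTAACCTTATGTGTTTGGGTTACTCCGATCGACCTTTTTTAATAGCAGCACTATCATGCTCACCTATTAAAAAGTCTTAA
GACTGTTAGATTGGTTACTTAATCGATTGCGTGAGCGCTCGTTTACTATTCAAACGTTTCCAGCAGGGTATGCCAAATTT
ATAAGAGTAATAGAGTGCTTTGTTATTGCAACTTTTATTGTATTTAAATGTGGTATACCAGAATTGAGGAAGGACGTACT
GTTAGATTTCAGCTTTGTCGACCCTAGATG
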