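>L1_consensus_synthetic length=6019 note=synthetic stand-in consensus, not a biological L1 sequence
TTGGAAAAGAAAAGTTCATGGTAATGGGCACGTGACCCGGATACCCACGACATCTTAGGGATGCTTTATT
TTACAAGAACTATTTAACGTTGGTTGCAAATTGATATCTTTCGTGCGATCTTTTATGTATAGATAGCACA
CAACCAAAACTTGCCTTATGGAATATTCTGAAACAATGTGCTCGTGTAATCTGCCTTCTAACAACCGGTA
GCAGTCCGACCCATTGAAAGTCTTGTCGGATCCGCGCTTCTGAGTGTTCATAGTAGGTAGATCTGAGTGA
TATTTCGAGGGAAGAAATGTGGGTTTAGTTAAGAAATGGCGATACGGCCGTAAGTTAAACAGATTCACAC
AGGAACGCGCAAATAGGACCGTTGTTCGAGAATCAGAAATGCAGTATCTTAAGCTGCCTTAGAAAGCAAA
CTACGAATTATTTTGCGCTCCACATAGAAGTAATTGAAGCATTAGACCAGTCACATCAGTTCCTATCTTG
TGATCGGATATAGGCAGCCTAACAAAATCACCAAACACTTACATACACAAGCCTTTGATAACTTCCTGTG
AAACATTTTGGCACCTCCTATTTAGAATTATCAATACCCATCCGAGGCGGCTATGTTCGACCGTTTTGGA
AACTGGACCTCTTAACGAAGGATGTCAATACATGATGCTAAACAGTAGACGTGTGGTTATCGTAGCTACC
CATGCTTTGCAGCACACCTGTTTGTTAAGAGTTCAACGGAACAGCCTGCCGCTTGCACATCTAATACACT
GGGTCTTGTAGAAACCATCTTGAGATACAATCTCTCACTCAATAACTGGTTGCTAATGTTGGTTAAATCA
GAATGGCACACTTTTAATTTATTGACACTTCTTTACATGTAAACCAGCCTCGTCGCAGCTACAAGAACCA
CAGTCCTATCATGGCTAATGTTTAGTGCCAAAAATGTTTTGACAATGGTGTTAGTCTACATCGATCTTAT
GGAGTCAGTTATCCTTGTAGCGAACAGTTTCAAGAACTTGACACACCATGTTAAGTGGTAATACGAGTGA
GAAGCGTAAACAGATCATTGGCGCTGGCATCAATATGAGTGCATCTCGATAGCGCTAGACAGGTCTGACA
ATCCAGTCTTATGTCAAGCACGATACCCTGCGTTAGATTACCCAGTAAGAGCCGAAGAAAGAAGGTATTT
AACTGCCACGCGATCAGGTATCAAGGATGTTAGTAAAATATGAATGTGATCCTGTAGTCCTACGATATGT
TTTAGTTTACGGATGTCGTACTGTAGGATAAGAATATAACCCTTTATATTAGCCTCAGAGATAACCTGGA
TTATAATGAGTTCACTAGCACTTAAGTTAGGCGACAACTCATTGCTTGTTTACACTACGCTGTCAGATTA
ATTCTTTGTCTGATGAAACAACCATGCGCTCAGTTGTCGCGCAAGAGGACGGACAAGATGGCCTTCTTGG
TAATATGCTGCGTCGTCGCTCCCATAATTGATTTCACCGATACAGGGTAATGAAAAATACTGGCTTGCCA
CCACCATACCATCTTTAAATCGGGCGCATGCTGCATTGTAAAGAAACTCCGTGTTTTAAAATTTTAAGAG
TCGAGTCAAAAGAGCACGTTGCGATTTATGAGCTCATCTATGGTAAAATTCTCATGACGATTTTTAACTA
CGATCGATAGTAGATTTGTGGTGCTATTTAAAGTGACGATCCACTCGTCAGTATCGGTAACAATTTGTAT
GTTCGGTGGGGTTATCCCCAGCGTCAAATATCTGCGCGTGATCCACTTGATGCCGTAAAAAGAGGTACTA
GCCGTCGAGCGGCATCAACTTTTGGGGCTTAAGGTACATCCGATTGTCACCTCTGTCTTCACCAGAACAT
ATGAAATGTGTAACTAATAGGTTCCTACTATACCTGACTCGAAACAATTCCCTCGCTATGTATAAATTGT
GGACCCACAAGTTTTTTGAAGACTACCGCAAAATGTTTCAATGTTTTTTGGTTGACCTTCGAATAATTCA
TGTGAGAGCTTACCCGAACGCACCTGAGACTCTCAAAAGGGAGCCGACAGTTCCGGGTAATAATAGAAGC
GAGTGCGACAACTTATATCATGCATCTTCGTTTCGAGGCTATCTCCCTTTCATGCATTCCAGCACTCTGG
GTTGATATGCAAGAAGCCAAGTGAGCAAAACAGTTTTTTAGAGGTATACTCAGTCAGTACACGGCTTTTG
AGAGTTCACTTTAGACGGGGATGCTCTGGCGATGAAATGGTTCCAGTGTCTCTATTTGGAATAGACGATA
TCCAAATATCGTATATAAGATGGATAATGAGCAACACAACCACAAGGTGTCTGCCTCTGATCTGCCTCGT
TTGCCTCTCTGCGTCACCTCCAACCGATGAATGACGTAATTATATGCAATGACGTTTTATGCGTCTTACG
AGGAGCCGAAAATAATGCTTACAAGACGACCTAATATTACCTCTTGAGTAGTCAAACGAATATTTCAGAG
ACGACCCCCGCTATCACAACTAAGTACGGATGACTCCTGAAAATATCATGGTAAATTTTAACCTTCGTGT
AAGAAGATCTGCCCCAAACTCCTGGCGGATAACGTCCAGTCAGGAAAGTATAGCTTACTGTGGGAGTCCC
GTAACCAGAGGTCGTACTCTTAGTCGAAATATATGCACAGAATAGTTAGCAAAGTACCTTAGAGACCGGA
AACGGTCAACTACGGTTATCGTACAAAGGAGTATGAAAATATAGGTTGTAGTACCTCCTAACCCCCAAGT
AGGAAGGAAGCACATCGGGCACCCGAGCTTTAATATGCTATGAAACTCCACACCTCCTCCATGCCTCAAA
ACTAATTAATTAGGGCAGTGGCAGTCACACGAATTCGACCATTGACGAACTGAGACTTAATCAACATAAT
GTTAATGAGAAACGGGATTACGGATGGGCCTGAAGCTAAACATTACACTTGCATTCTTGATACGCATTTC
ACACGTGTGCCGCAGAGCTATATTTGAGTGCCTTTACAAGCAGGGGCTGTCTACAATGCGGCAGTAGCGG
GAAGATATCCACCTTGTACTTGTACGCTTTCATCGTAGTTCCTGAGATTACCAAGAGTCTAGAAGTCACT
ACCCGTGGTGATTGGCGCATTGGGAGCCAGTGCGTTGAAGAAAGAAATAGACCCTTGTATCTAAGAGAGT
TTGGTATTACGCTAGCAGAACATTAACACCGCCTATTACGAGGTTGACTTGAAAACTGAGAGGTGCGCGG
CCCTTATTCCACTTATTATAATGGCCGTGAACTGTTCACACTAGGCCGCAAACGAACTAGGAATGCAAGC
CACGTCTTACGCGGAAGGTGTGACGAGCAAGCTGTGCAGGGCGCGATAGTACCAAAAAAGGTGTCAGAGA
CTATTACTCGAGCTAGGTTCAACACACTGTAATGCCTAGGTTTATCAGCGGGGCGCTTTTAGATTCGTCC
GTGGTTCTTTGCCGAATAAGACACATATTTCGAGATACATACGTACACGATGTCCTTGTTATCCACGATT
CAAAGTTGCTTCGTTATTGCCAGCAATTTCTTTCTGAGCTTAGGAATAGGTTCTACTCTTTAAAATGAGG
ACGATCAGAGAGGTTGAAGGACAACGGAGAGGGATTCGATTTGCGGGTGTCTGGCGGGGCCGTCCCACAC
TGCCGTTTGAGACCTGGGTAGCTTTGATTTGTTAATTCATTATGCATGAGCAAATGCCAAGAAAACACGT
CGTTTGGATGAGGAACTAGAGCAAATGTCACTGACCGAGACGATTGATGTTCCATTGTAGCTTCAATATC
AGTAACCGAATAATGAAATCCCCGCGTTATAATCACAAGAGTCTTGAGCCCATCATATTCGACTCAAGAC
TGCGGACATGTGGCACAATTAGTTCGCTTTAGGTATCGTCCACTCTGACGTGGGCTTGCTTAATACATCA
AATATGAACCTACAGAGTCAGAAAGCGATTGATATGTCGTCAGATTGCCCTACTAAACGGAAGTACTCCC
CTTCCACCAATCGCATTACTCAGAAGGAGCGGCATTTCAGATGTCTGTTTAATTACGTGTCAGGGTTGAG
AATCAAAGGGATTTCGAGGAACCGCCTTCCAGTGAACCTACAATTTGTCAATTATCAGTCCAACTCCATA
AAGTTTTCGTAATCTCCCTTGATCATTATCCTGTAGTAATAAGTACGATTACGGAATTAATTCAAAACGA
GAACGAGAAAAACTGTATTTCAGTTTTATCACGTGCCAACCTACGGTTATTCATTTTACTTAACCATCGC
AACACACATATCATGTTTCTATGGCGAAAACCATCTCAACTTGCCTAGCGATGCTGCTGCCTGCACTGGG
TATTTCGTGGTATATTGTGAGCAAACGAATTTATAAGTATGAGTAAGGGTGTAGACAGGGGGTTCACCGC
ATCTAGAGCAAAACATACTATTATGTTCGAGTATTTGTTATGCATACGTATAAGATTGGATAAGACCTGG
TGAACGGGTAACTAACAAGAAGGGCGCTCCAGGCAGCCAAAGATAAGACCGAATATGTAGCGCATCCTAA
AAAGAGCTCATTGGGGCATTCAATAAGCATTTAAGCCACGATCCCTATCGAAGGGTTATTTTGGGAGTCG
TTCTTGGAATATACTCCCGTATCTACGATAGCACTGGGTAAGCAGGAGCCGAGGAACTCGAGTTTCTACG
ATCCCCAAGAGTTTTGTAATCAGCCTGGATTCATTAAGCGACCACCTGGAAAAATGGGACGGGAATGTTC
TTGTACCGCAACCGACTGCCCGCAGGTTAGGTATCTCGCATACACTATTTAAAGAGATAGTGTAGCTTGA
CGTACGGCGCTGCTTATAAGGACTACGTAATTTCATACCTTCACAGTCCAGTGGCCTGGCTTGTAAGTGG
TCTTTATATCTCTGCCTCGCCAGATTGCACACAAGCTGCTAATTAAGAGTAATAACGAACATACAGCTAC
AGCAATTACTTGTACAAAGAACCCAATTCGCAGAAATAGTAACTTATTGATGAAATTAGAGTCGGAGTAC
GGCAGTTCTGCTGTTGCAAATCTCATACTTATGTTAATAGTTCCGCCTTATCTGACGTCCTATCTATATA
ATGCTTGGTTCAGGGAAATGCTGATGTACGACGTACCTTATACACCCTTATAAGCTGTCTCATTTAGCAA
TATAACACTCGCGCCGTGAGTCGTACACAGTAGTCTATAAAACCTCATAGCATCCATATTGAGTGCCGGC
GATGAAAATACGATATCTCATCTACCTCGTACTTTCACATAAGTTGTATGCTTATGAGGCACACCATAAC
CATACTGTATTAGGCTGACTCGATCAAGTTCCTCTGTATCACAGGACATGCTCAAAGCACGGGGGCTTAT
ACTCCTGAGAGAACTACTGAGATGTTAGCACCGGGAATTATTAGCTGTGCATTGTTATATGATGAAAAAG
TGTATTCTTCGACTTTCAAATGAAATGGACGAAGAAACGATAGTTACATGGTCAATTCACTAGTACCATC
ATAAATCAAGGACTAGTAACACTGTTAAACGAGATTCCTTCGAATGGTAGCGGCTACTCGGTGAAGCTCG
CTGAGGCTCTGGTAGCTAGAGAGTTAAAGCCGAAACACGCTTACTTCGCCTATCCTTTTTATACTTGTTT
AACGTTCTCTTATCAATACACAGGGAACCGGCGACCTAACGTGCTCGTATTAAGATCCTCAGTTCTACAA
GGTAAATACAACGATACTTATCGCAATCTGTTCGTAATCAGAGTCAGCTACTATAGGCGGTATTAATGCC
TCCTTCTCACATCTGCACGGTTAGCCCAATACAAATGATCAAGACGGTTTCTAGAAAAGACCCTGGGGCC
GGCTGACTACCCCGAATGAAAGCCTCCACTTTGACCCAATAAAATCAACATACAGTACTAAGAAAGTCC
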