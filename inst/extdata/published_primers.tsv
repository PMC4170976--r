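locus	forward	reverse	panel
Ant21	TTCTCGGGAGCAACCGTGGT	CCATCACGCACTCCACCTCG	screened
Ant608	AGCGGATCTAGTGGTCTTGG	ATGGAGGGGAGTAAGAGCGA	screened
Ant1049	GAGGATGCGGTGGTGGCGGA	CTGCGCCGCTCCGTGTGTAT	screened
Ant1052	GCGACCTTCGTGCACGGTATC	CTTTTAGTCAGACGCACGCG	screened
Ant1387	ATAGGTGCCACATACGCGTG	CACAGCCGACTCCCCTCTCC	screened
Ant1732	ATGATACGCATGCGAGTGCC	GCCAGCTCCTCCGAGCCTAT	screened
Ant2409	ATCAGCGTCACGATCGAGTT	CGTGATTCTTCTGACGCGAC	screened
Ant3362	CCCCAAAACCTACCTCGTCC	GTCTACAAGCTCGCGATGGA	screened
Ant3395	CCRACGGGCGTCGGCAGTCC	CCGGCACTTGGTACACGGTA	screened
Ant3411	GCGGCAGCAGCGATCACCCC	TGCAGCAGGACCGCCGTRGT	screened
Ant3452	TGTGGAGTGCGGCARTGGGA	ATCGACGACAAATCGTGGGC	screened
Ant3505	TTACCGGACAATCGTGGTGG	TGAGCACAGCACGACATTCT	screened
Ant3541	TGCAACAAGTGTCCTGAGGT	TCACATGTTCCGGCGYGCAT	screened
Ant4709	ACGGGGTAAAGGGTTAGGGA	AGCGATGGGAGATTGGAGAG	screened
Ant5033	TTCCCCTCTCCCTGACCACC	TAAGACAAGGAACGTCCGCG	screened
Ant7204	GCCCAATCCTCTGCATTCCT	CCCGCGAAAAGTCCATTTCGC	screened
Ant8544	GGGGTGCGTGCCAGTCTCGT	CAATGCGATCTAGGTCACCA	screened
Ant9564	TTAGAGGCGCCAGSCTGCT	AGCGAGCAACTTCGATGACT	screened
Ant10290	CGTTTTCAAATTAACGTTTTTGCC	ACGCGCGCTTCCGCGCTCGGG	screened
Ant10427	AATCAGCTTAGCCGCGCTAA	ATCCACCGCATCTGGGATTC	screened
Ant11610	GGATAYTGGGGCGGCGTCAA	GCCGAAAGTGTGGATACCTC	screened
Ant20	AGGTCCTAGCAGGTAACATTG	CCTCGGTCGATCGAGCGAGC	characterised
Ant575	TCAGGTTCGACACATGTGCC	TCAAGATCGTTTGTCAGGCTGA	characterised
Ant859	TACGCGGAGAAACGTCTGGT	GTGATCTAAACTTCGATGAAC	characterised
Ant1343	TCGGTCCCGTGCCTTCGATT	GRGGGCGCGTCAAATTTGCT	characterised
Ant1368	ACTACCCCAATGACGACACG	CTATGCAGGTGCGGGTGTAT	characterised
Ant2341	RAACAGCAGCTGTCCGGAGG	GTCGCTGATCGCCACGTTCC	characterised
Ant2794	TGGTGTGCGTGTTTGCRAGG	GACTGCCAACCTACGGACTC	characterised
Ant2936	GGGGGATCCGGTAATCCTCT	TCGCCCTGCAGTTAATGTGT	characterised
Ant3648	CTCCTGGTCCTGGATCTCCA	TAACACCATGCCCTCTGTCG	characterised
Ant3653	AGCAGAGACCAATCAACGGA	GGCAATTATCGGACCGGGTT	characterised
Ant3993	TGATCCGCTCTTAAAATTTAGATGGA	ACTTTCCGCRGCATTAAACATTTTCTT	characterised
Ant4155	AGAATCTCTTGAGCCCGTCG	GGCGATACACTTCACCTGAGAC	characterised
Ant5035	AGGATAGTTTCGCGGTTTATGG	ACTGACTCGYAGTGTATTTGAGGT	characterised
Ant7249	AAGTGTCAAGGGCGACTGAG	CGGGGACAATGGAGCAATCA	characterised
Ant7680	TCCCGGAGCAGCAATTATCC	TAGGACAAAATGGAGCCCGC	characterised
Ant8424	TCATAATGCAGATGATGGAACTCCT	GGCGAGTAACACAATGGCAC	characterised
Ant8498	GATGCGAAGAGAGGCACGCG	TGTTGCGAACYTAGGTGGCCTC	characterised
Ant9181	TGCCACTTACGCTGTGCACAC	AAATGCGGCCGAAGAGAAGA	characterised
Ant9218	GACCCACTTTGCCCTCGTAA	CTCTCGATTAGTCAGGGTGGC	characterised
Ant10878	CGGGTGYTAGTCGTCGCCAT	GATCAATGCCGCAACGCTAA	characterised
Ant11315	AGCGTGTGCGACCGTGTAGC	GCCATATATCATGGCTTGCCAG	characterised
Ant11400	CAACCACTTTGGGGCGCGAG	CGAACCTCTTAATGAAATTCTCACCC	characterised
Ant11893	CAGGCTCGGRACGTTAATGC	GGTGCCGACGTCTAGCTAGC	characterised
Ant12220	AAAAGAGGCGGGCGTTCTTA	GGTGTTCYGCCCCACCCGTA	characterised
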