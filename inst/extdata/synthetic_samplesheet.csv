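name,sgrna,primer,amplicon,cut_index,pam_side,direct_positions,mh_min_len
synthetic_psy1_like,TGGCTATTATATGTTGCCTT,AATCACTATAGTATCACGAT,AATCACTATAGTATCACGATCAAGGTCTCCTAAGGTCCACAGACTCACTGATAAGGGAGAGTAATCCCTTGGTAGCAGTACCGCAGTTATCGATGGCTATTATATGTTGCCTTGTTAGCCGCCTTCCGGTAAAGGTAAGTGAGTTATACGTGTGCCAACCTCATTGTAGCCTCATGGATGGTGCCGCATGCTTAGTTTATATAATCGCTCGATGAAATTG,110,right,0,2
synthetic_crtiso_like,AGGTTAGTCACTTAGCTCCG,AAGTTTACCCGGAGGGGTTT,AAGTTTACCCGGAGGGGTTTAGTAAAACTTGACCCCGTCGCACAATCGACTGGCCACCGCTTTCGGACGTTCGGGGTGTATCGTAGCATGCAAGGGAGGCGAAAGGTTAGTCACTTAGCTCCGGTGTCTATCACGCTTCAACGTACGGCATCGGGTGCCAAATCTTGGTGGGGTCCAAATTGCTAATTAAGAGTCATCTCAAATCATACTCTAGGACGGAGGATGATGTATACAAAGAAT,120,right,0;-1,2
synthetic_phyb2_like,GCATTTTAGCACGCGTTGTG,CGCAGGAACGGTATGTACGA,CGCAGGAACGGTATGTACGAAAACCTTAATGGGTTTGATAAGCACACATAACTCATATCCTGCCACGTCGTTATCCTGACTACGCATTTTAGCACGCGTTGTGGAAATGTGTTCGTGGAGAGCGTTGAGTGGTATTTTACCTCATTCAAGACCCAGGGCACATTACCAATTTAAGTCACGTCGGTGCGGCTTCAAAACTC,100,right,0,2
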