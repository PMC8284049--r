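LOCUS       nptii_tu_alpha1  1570 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  nptii_tu_alpha1.
ACCESSION   nptii_tu_alpha1
COMMENT     gb_level: L1
COMMENT     gb_backbone: alpha1
COMMENT     gb_marker: kanamycin
COMMENT     gb_provenance: NA
FEATURES             Location/Qualifiers
     misc_feature    1..980
                     /label="alpha1_backbone"
                     /gb_role="backbone"
     misc_feature    61..660
                     /label="KanR"
                     /gb_role="marker"
     misc_feature    988..991
                     /label="OMEGA5"
                     /gb_role="fusion_site"
     misc_feature    992..995
                     /label="VEC5"
                     /gb_role="fusion_site"
     misc_feature    996..1555
                     /label="nptII_TU"
                     /gb_role="TU"
     misc_feature    1556..1559
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    1560..1563
                     /label="ALPHA_MID"
                     /gb_role="fusion_site"
ORIGIN
        1 aaccgagcgc atccagtatt gaaagggaga tgacaaagct cggtgtggag gcggtcgaac
       61 tcgctgcgtt ttcttccgaa tgcctggaca aggccctgcg tactcgcgag cctcattaaa
      121 tatagctcat aaccccgggc catgcgtatt actgagcgca tgccttcttg gttaggtgcc
      181 ccagctttac gaatccggcc ctggttctca tttacccctg cactctgttg gtgtctcacg
      241 tgagagatga atagattcct cgaatatgtt ccagctggac gacgtggtac attcttaggc
      301 acgttatgcc gggtcctcta tcattgagag aaaccctttt ggcacccgcc gaaaggagaa
      361 cgtctagggt gaccgtgagg tggaccgaga ctgctggtgc ttgccgttcc acgcagcagg
      421 ttactagtgt gtggtgtgga taacataatc ttaatagtaa tctaccggcc acccacgcct
      481 gaaaacgaag gtgggtcaac aaggttacca ataagacctc tctatatcgc ccgtacagaa
      541 tcgagtttat tgccaccata gtatacagga aggccgccct atgtatatac tcagaaattg
      601 taggacgctc ttgctgggcc tggagggcga aacgtatggg aggccaaggt cgggcggctt
      661 gccggctagg gacccatcgc ggagatgacg atgcggccgg aaagacattt gcagggtgta
      721 gagctcccat gaatcattta ttagatggta gatgcagggc cttcgcacgg cgattcgcgg
      781 atcttgtaaa ggaaaggggt tgccgctttc actgaccgtc cgcacctagc gagttataaa
      841 aacaattcaa agaacggcaa gtagcggtca gaccattaaa cattacttga gtatgtataa
      901 ccaccgccct cgttacgttg tcacgaacta cttaccattg aagactatag tctcgtgggg
      961 aggcagtgcc attcccgaaa cgtctcacag gggagaatct ccaatgagtc tattggtcca
     1021 atattagcca ctactagaag gcgatatgga cccaagaaag gatattattg gtaagcaaga
     1081 gaggacgtga cggtatcata caccagtatt acgctataac taaagccccg tactgacaat
     1141 acggaccgca ggatcttgcc atgccattcc caggtcgaaa aggtaagttc aacttacctt
     1201 ttaactcgag gtccatagga taataggaag cggagccctt ccgcgatgca cttgattctc
     1261 agcgcacgac cgacgattta gcctcatgaa tggttcgctc atgagaagta tttccgtaac
     1321 gtacactctt cgttgtcgtg ctcgtacgca caccgcagcg ctcccgtaca tcctacgaag
     1381 gtgcaccacg ctcagtaaca aaatgatcgg gggcctaagg agtcctggcc ttatcaggcg
     1441 tagccattgg agacttaaat ccggcgtagt agcaacgccc tatcaccaac cggctacagg
     1501 ctgagggagg atggaattgt accttgggtt ccccagaaga ctgtcaacga attaacgctt
     1561 acatgagacg
//
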