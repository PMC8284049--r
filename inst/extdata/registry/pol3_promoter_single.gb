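LOCUS       pol3_promoter_si 1030 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  pol3_promoter_single.
ACCESSION   pol3_promoter_single
COMMENT     gb_level: L0
COMMENT     gb_backbone: pUPD2
COMMENT     gb_marker: chloramphenicol
COMMENT     gb_provenance: NA
FEATURES             Location/Qualifiers
     misc_feature    1..820
                     /label="pUPD2_backbone"
                     /gb_role="backbone"
     misc_feature    61..660
                     /label="CmR"
                     /gb_role="marker"
     misc_feature    821..824
                     /label="UPD5"
                     /gb_role="fusion_site"
     misc_feature    832..835
                     /label="VEC5"
                     /gb_role="fusion_site"
     misc_feature    1016..1019
                     /label="PROM_GUIDE"
                     /gb_role="fusion_site"
     misc_feature    832..1019
                     /label="U6_PolIII_promoter"
                     /gb_role="promoter"
     misc_feature    1027..1030
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aattacttga atgacgtgtc atttccgcgg ttcgaagagc gcgccggggc ggtttcgttc
       61 cagagtagta tcgacttgct gaattttaag gtggttagag tatagcttac tactctggtt
      121 cctgaacctt agggaatagt gtatctttgc cttccagttg gcacaagacg gaactatgag
      181 tcatggacct gcggccggag actatcgcta aaagtattaa tttgtcatcc aacccagcaa
      241 agaaaatatc accggggttt ttgccgtttt aatcgctgca ttcgtacgcg tatggcctca
      301 caccagcggc cggagccagg gtcttacacc atcgccggat tctgactgcc cccccgcaac
      361 gatttgggtg gaggaaggac ggatgtgcac agaaaaccag aagccctgga gatagtccct
      421 ttgattgtat gcgtgccttg tgttagtaac tttaccagct ccaagtcgtg ttggccggta
      481 attcgtcggg cccccaggcg agcttcccac catactgggg ttacatgcat cacctagttt
      541 gaattgtaat aggctgttaa tacgcacgag cgaatcatcg ctgagaaatg atcttctccg
      601 ccccatagcc cgtgcactca attaactcgt cacctgggaa gaaactcgta gacgcaaccc
      661 ctcttagaag gctagttgca tgtcgaggtg actgtttccc acgcacttcc gcttaataag
      721 ctgttaaggt cttgattaaa tggggggtga atgaccacag gctcaggggt atgaaaatct
      781 cgtgcaagga atgttctgtc taccaggata gacacaggaa ctcgggtctc aggagaacta
      841 gaggcatccg cgtcctccgt cggcttgggt ttcacccgat gtcctgaact gggaaagtgg
      901 gtgcctctac cccacgcggg atcgcaaacg tgaaatattg gcggggcgac cagcacctca
      961 agggcagtgc tcaaataagt tgaccagcca atctcgaaaa cgtttctgtt ggtaaattgt
     1021 gagaccggta
//
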