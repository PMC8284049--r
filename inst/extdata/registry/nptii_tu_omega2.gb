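LOCUS       nptii_tu_omega2  1570 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  nptii_tu_omega2.
ACCESSION   nptii_tu_omega2
COMMENT     gb_level: L1
COMMENT     gb_backbone: omega2
COMMENT     gb_marker: spectinomycin
COMMENT     gb_provenance: NA
FEATURES             Location/Qualifiers
     misc_feature    1..980
                     /label="omega2_backbone"
                     /gb_role="backbone"
     misc_feature    61..660
                     /label="SpecR"
                     /gb_role="marker"
     misc_feature    988..991
                     /label="OMEGA_MID"
                     /gb_role="fusion_site"
     misc_feature    992..995
                     /label="OMEGA5"
                     /gb_role="fusion_site"
     misc_feature    996..1555
                     /label="nptII_TU"
                     /gb_role="TU"
     misc_feature    1556..1559
                     /label="OMEGA3"
                     /gb_role="fusion_site"
     misc_feature    1560..1563
                     /label="VEC3"
                     /gb_role="fusion_site"
ORIGIN
        1 aaactccact agtattaaat attaggttgt cctagtagtt ttgacttcat atcatacgta
       61 caacaattcc tactctgcag caaatacata ggaaagttac caactaaacc taatagctca
      121 gaaacctcct tgaagaacgt gaaggttacg agttcctgag gcggccaccc tgaaacataa
      181 actagccgca cttggagatg ctgcggtgct aataacggaa cgcctcacat gtaattattt
      241 aacttcctac atcgtacgaa gcctgacgta aggtctttgt agaggactct gagagatata
      301 ttcgttattc ggttgacgcg ccagggccaa cttcatattg atcacccacg aaaccaaccg
      361 acggcatccc ccgtgattcc gtgcacgcac atcagtcttc ccccatgctg ctacgtactc
      421 ctacgtacga atgagatcat gagctgagat agattgtcag caagaaagtg cgagtcccca
      481 atctatcggc tagttagtat acaccttttt tttgcggcgt aaaagttctt agggttaata
      541 ctctatccta aggtaaagat taagcagcaa gactttgtat cctcatacta agtaagttgt
      601 tgttcgacgg gtttcgcccc aggtaatcac gtaacatcga gatcctccct ttttaatgta
      661 tctcggatag taatttcagc ggcctctgct gctaatgcga gccaaaagca cttggtagga
      721 gtcctattaa aagggcagtt tcgacgacgg accaagccgt ggcgtcgctt cccacctact
      781 ccgaaccaaa cgcgggctca tgcgattcca gtaataattc tgtcagcgaa ctattctaat
      841 tcccaatgtg gagtcgctga atgggcgaca tccgcgacgc gcttcttact agcacggttt
      901 cgggcgatta acagagttag ttcgcagcca cggtgggatc cgagttaaga acacactata
      961 aaatcccttc aacacggaaa ggtctcacca tcaggaatct ccaatgagtc tattggtcca
     1021 atattagcca ctactagaag gcgatatgga cccaagaaag gatattattg gtaagcaaga
     1081 gaggacgtga cggtatcata caccagtatt acgctataac taaagccccg tactgacaat
     1141 acggaccgca ggatcttgcc atgccattcc caggtcgaaa aggtaagttc aacttacctt
     1201 ttaactcgag gtccatagga taataggaag cggagccctt ccgcgatgca cttgattctc
     1261 agcgcacgac cgacgattta gcctcatgaa tggttcgctc atgagaagta tttccgtaac
     1321 gtacactctt cgttgtcgtg ctcgtacgca caccgcagcg ctcccgtaca tcctacgaag
     1381 gtgcaccacg ctcagtaaca aaatgatcgg gggcctaagg agtcctggcc ttatcaggcg
     1441 tagccattgg agacttaaat ccggcgtagt agcaacgccc tatcaccaac cggctacagg
     1501 ctgagggagg atggaattgt accttgggtt ccccagaaga ctgtcaacga attaactcac
     1561 gcttgagacc
//
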