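LOCUS       cas12a_tu_alpha1 1650 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  cas12a_tu_alpha1.
ACCESSION   cas12a_tu_alpha1
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
     misc_feature    996..1635
                     /label="Cas12a_TU"
                     /gb_role="TU"
     misc_feature    1636..1639
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    1640..1643
                     /label="ALPHA_MID"
                     /gb_role="fusion_site"
ORIGIN
        1 aattacatgc aggaagattg aagttcggca gtgcaattta taaatcatga gtgatagata
       61 gccactcccc aatctgtccg tatcgtgtta gtagatctga cggggattat agtccaaact
      121 ccactattta taagaaatat ggcggttata ggagattaaa ccaccatgtc taaaaacacc
      181 taagggcagg tgatggatga attcaaacga tacgaagaga cagttgtcaa tgcgagtcta
      241 gagccgtcga tgttggataa aggtggaata tgccccaaga tatacttggg ttctcttatg
      301 ctcgaatgac tgacaacgag tggccgttcg gacttccgca gatttcatta caacccaatg
      361 actacaacag aatcgatgcg aaaagtattc ccttatggat tgagtttgcc cagcattttg
      421 caatgtttgc cgtcaatcct cctggacgat caatgctcgt taagctgctt gagggttctc
      481 cgaggatctt atggtgaagc ttagaagaag ggggccaaac ccactactct gtaacgactc
      541 gaggtccagc caccaatgtc atttatctca aagcgcagaa gcaatcggcg atgcgaggtg
      601 atccgctcaa taaatgtaga tcctagattc ccagtgccac gtattcgagc atgttgcgta
      661 cttatagacc aactctacga gtgagctccg tggtcggtga gtaggcgata gacttatgtg
      721 gcgcgcaaga ttggtagcaa acaatcaacc ccttcgtacc tcaaataagt gttcttgtcc
      781 tctccccttt aacggcgcgc ccatcaaagt ctgtactgtc cgggtacttt gcggccttac
      841 aatggatgtg ttttatgatg gttatgtccg ctcacatgga ggatctattt ttcccgcgtt
      901 ttcctcgact tacctcggga aactctagtt cttacgctaa atttaaggat cggatcaacg
      961 tgtggtggtc tttcaagaaa cgtctcacag gggagaatat cgttcagtag caggggccgc
     1021 ccttaaaggg gcagatttaa gagaaatctt gccgagactc gattgttacg gtgtatggtg
     1081 taaaagataa ccgtcttttg tcatgagagt gccaccagac aacaaggcta tcgagtgtgt
     1141 aattgatgtt gcgacgtgaa ttaaggaagt ggtcggtatc tccctttcac tggaacgccc
     1201 tagtcagcag ttcgaaagag atccttccta aggggattag accttatgta cgatccgtta
     1261 tcggcggcgt cattacgcag gccacgcgtt tccttgacat tcgtacacgc catggtgcac
     1321 tacagatccg tgcaggatag gactaaagta aggtgacgtg tcttcagttc ctatccatac
     1381 tacctcggac tgttgcccat cttgccagag atttcatcca aacgttcggg tttccaatga
     1441 ggcgttaaat tcatcaacgc agcaatacac ctccatacaa cttcctaacg tccactatat
     1501 cttaaactaa cgtgctagac acgctctatg tacttttaaa aagaaggtgt gcagctccgt
     1561 gtgaaagagg atggcgacac aggctattgt gatttatacc gtgaaacgtg gagtatgctg
     1621 ttccttcaca acaaacgctt acatgagacg
//
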