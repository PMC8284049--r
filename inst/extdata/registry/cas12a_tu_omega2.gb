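LOCUS       cas12a_tu_omega2 1650 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  cas12a_tu_omega2.
ACCESSION   cas12a_tu_omega2
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
     misc_feature    996..1635
                     /label="Cas12a_TU"
                     /gb_role="TU"
     misc_feature    1636..1639
                     /label="OMEGA3"
                     /gb_role="fusion_site"
     misc_feature    1640..1643
                     /label="VEC3"
                     /gb_role="fusion_site"
ORIGIN
        1 aaatctaact cttactcacg tgcgtcgacc caagagcggg aagagcgccg gctctattta
       61 tacatggacg tactgcggag tgggtaagca ccccctgtat aaatgttctc actgtgtgga
      121 tactatttca ttatgccgct tttgctaatt tatgtctagg tatgtggtct tatctacgca
      181 gttacgttaa acccacgcca gtcgcggtct tcaattaggc agtattcctt tactgaacgt
      241 gacccataaa tcggagtgga gctgtgattt cgacagacgg aggccttgtt ccattccgtt
      301 ctgcgagtca cggctccata tctttgtgcg taggtcactc gttcttaatg tttaaagtcg
      361 actcgactcg atcgtgaccg atcagacatg cctgggtaca aacagtagca tttcagctat
      421 ttctttattt gtaaaagagc taggcctaca ctgtgggtgc agagagcggc gctctattcc
      481 agatttccac cttggtcgag ttaaatacaa gaactaggta tccggatagg aatctactaa
      541 cactcggctc cttcgccaaa tccggacagg tctgagagcg ccgtagaccg gatgagtgag
      601 gccatagccg agtactggaa agcgctgggt gaaaggccag ttcaggggag tttactttca
      661 atttacgtcg cttcttaaag agagcgtcct atccattatg gagttgcatt agcgccactt
      721 cgatatttcg aacagacgca gtgaggaggc gatgtcgacc ccggccccat agcccattac
      781 tattagaaga ttcagctcgc tttgatattt taatgtaaga ccgtctagta ctagcatgca
      841 ttccccaaac gtgccggagc ggcatccaag gcgagtctcg gtgcctactc ccggcgccaa
      901 acccagtgat gcgcgcggaa atagcgtgcg gtcgccggct gaccgtatta tgaaccgtat
      961 ttaaaattgt gtcgggtaaa ggtctcacca tcaggaatat cgttcagtag caggggccgc
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
     1621 ttccttcaca acaaactcac gcttgagacc
//
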