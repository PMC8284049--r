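LOCUS       cas12a_tu_omega1 1650 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  cas12a_tu_omega1.
ACCESSION   cas12a_tu_omega1
COMMENT     gb_level: L1
COMMENT     gb_backbone: omega1
COMMENT     gb_marker: spectinomycin
COMMENT     gb_provenance: NA
FEATURES             Location/Qualifiers
     misc_feature    1..980
                     /label="omega1_backbone"
                     /gb_role="backbone"
     misc_feature    61..660
                     /label="SpecR"
                     /gb_role="marker"
     misc_feature    988..991
                     /label="VEC5"
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
                     /label="OMEGA_MID"
                     /gb_role="fusion_site"
ORIGIN
        1 aattctacag gagcgaccca gagcatcgag ttcactaatg aattgtattt actaacagtg
       61 atggcgctct tcggcgtgtc ctacttctag ttgagcggga ccgaagctat gggcttacgt
      121 agactccata atgcctgtct gtaatttgat gttccagtcc ctgatggcag catcccaacc
      181 aacgtttccc gagccacgac gccaaatatt aaggtaggta acaacattct gtgactccct
      241 gtcggaatgg ttcttaaccg tcgcttggct cataccaagt catgttgtta tatcgccccc
      301 accgcaacac ggtattattg aaactcaata agctttaggc gtcagcgagg gttgaagatt
      361 gccggcgagt agtgtcacgt ttttctcggc gtcatttctg atgcggccgg gaacaccccg
      421 aacgttctcg tcctatcggt tagcggagat ttgactgttg cactggtcag cggcggttaa
      481 cgcaacgcat gtatatcgcg cggtacgttg gaacgtccat tccttcatta ctttgcagtc
      541 tcccgcgtcg catcgaggtt agagcagtcg actctcaatg tcgtgagcta cggcgccgct
      601 cctagaccta acagacaaac tcaactgtga cctttctcgg accagtacgt catcaagacg
      661 cgccagttac gcgggcagcg aggtcccgat ttgtgaccat cttgataggc gacgttctct
      721 taacatggaa gatatcccct attgctgaaa agcatgctac cacgaccatc agtacaaaag
      781 tgcaattaat gcaaggtcac tggctcaagc cggtccctag gccacatata gctccaaggg
      841 gccatcactg cagctacgct gcgaagcccc atcgaaatga agggctgcta cctgggggtc
      901 ccacacgcga aacttatgga tcccatttcc acgtaaaaag cagttttaga tgtcgtaggt
      961 cctgatagta gacttcgtaa ggtctcagga gcaggaatat cgttcagtag caggggccgc
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
     1621 ttccttcaca acaaactcac cattgagacc
//
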