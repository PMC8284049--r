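LOCUS       cas9_tu_omega2   1730 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  cas9_tu_omega2.
ACCESSION   cas9_tu_omega2
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
     misc_feature    996..1715
                     /label="Cas9_TU"
                     /gb_role="TU"
     misc_feature    1716..1719
                     /label="OMEGA3"
                     /gb_role="fusion_site"
     misc_feature    1720..1723
                     /label="VEC3"
                     /gb_role="fusion_site"
ORIGIN
        1 aatcatttct cggctctggt acatggggca tattcagtaa caaccactag aagaggaatt
       61 attccgtact cataatcaat cctacgacgt aataggaata cttgaatata tccttggtaa
      121 cgaagcaaag gacgcaggtt acttcatcgt gctgcttaag tttgcgccag gctcataggc
      181 cgaaacataa ttctatacta tccagttggg gaagcactaa agcaccgtcc atatttcgtg
      241 atacaaatac aagtgctcct tgcctgggtc gcgcttgtgc aagcgctggc ggaacccgca
      301 agcgccgccg gggtagtata cgagtatact gtgggccata catcatagga aggcaactta
      361 cgcggccccc agggccgaat tgaaggcaaa ggtcggagaa ggtgggagct atccaagtct
      421 tttagctcga gccatgagat gtcagtggtt cgcattaaac gcagcgcggt catcgcaaga
      481 gagtttcctg caaccaatag cagtggacag caagttccat tcatgtggtc atgaccaggt
      541 gagcggttac accctaggcc attagtccaa cggaatagtg gacgcagtaa gtacttcgta
      601 cttgcggcgc ccaagtcagg aactgcaatt caaggtaccc gaggcttccc ttgcgtacta
      661 taattttagt agaggcgtta gaatatgtga tagtgatatg gatttacaag cccgcctccc
      721 ccggttcact agcaaccctg tcctactact cgactcatag cgccggcgcg ctacgcgagg
      781 cgcccacagt tgccatgagg cacctgtttg ccgcggtgcc cccgaggtag aaatccccac
      841 aggttgtgag ctcgttggcc atcgtaatgt tgactaacgc aagttgccgt aagggaaccc
      901 gtgtgtggac agaaaggagg gataaagagt tatccttgga gattgcgact tctgtagcat
      961 acatcaaatg gccgagttaa ggtctcacca tcaggaatgg gcgatggggc gaaataagag
     1021 gcgattatcc atggtccatc agacgcgtgc ctgcacctct cggctctcga aatggaagag
     1081 cttaggctat tgtaagaacg ccctagacgg gattcgatct aaaatttcat atgagggtcg
     1141 gttgtaacta tgcgtctact tccccggtag gcactcagca gccaactggt agagataaga
     1201 gttcgaagta agacaagatt taggcgggcc agctataaac gtcgcgatca gggacgcctc
     1261 gcatgaacgt aaccgtcacc agcgccagtc caacagaagt cagttagtcc atttggttcg
     1321 acggatgtgt gataacgaga tgtagtaagc ctttctagag tacgagtagc ctggtggaaa
     1381 aagtccggca cccgcggccg aggctggttt tcgggtgcgg aagttgcgca cgtctttttg
     1441 cgttagtttc gcgaatatag aaacctatct ggcacacgtc tttttacctc tgagtctggt
     1501 cttgaaagtg gtgttttgtg aattatcacc tggggcgccg cgcttgctgc aagaaccaag
     1561 gcggctttgt aactgctgta tttccaccct tacatgacgg aggcagctgc cgaggaaggg
     1621 tacactacgg aggtgtgatt tagcgcgctg gtttagggag gcccatacag gcattggaaa
     1681 gctagttttc ttggtgccga ctaatttggg gtcaactcac gcttgagacc
//
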