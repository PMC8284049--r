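LOCUS       cas9_tu_alpha2   1730 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  cas9_tu_alpha2.
ACCESSION   cas9_tu_alpha2
COMMENT     gb_level: L1
COMMENT     gb_backbone: alpha2
COMMENT     gb_marker: kanamycin
COMMENT     gb_provenance: NA
FEATURES             Location/Qualifiers
     misc_feature    1..980
                     /label="alpha2_backbone"
                     /gb_role="backbone"
     misc_feature    61..660
                     /label="KanR"
                     /gb_role="marker"
     misc_feature    988..991
                     /label="ALPHA_MID"
                     /gb_role="fusion_site"
     misc_feature    992..995
                     /label="VEC5"
                     /gb_role="fusion_site"
     misc_feature    996..1715
                     /label="Cas9_TU"
                     /gb_role="TU"
     misc_feature    1716..1719
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    1720..1723
                     /label="OMEGA3"
                     /gb_role="fusion_site"
ORIGIN
        1 aaccggagta tgtacggcag ccttcttttt agccccgtaa agaagatctg tagagagcat
       61 catgcgcatc ctgccgttaa gagtgacact gagtcgtact gcctacttcg ccttttccgc
      121 caaaaaggga gcgcccggcg gaacagacct caggaagcac aaatggggat acgtagagta
      181 ttttccaatg gttgcaatta gatttccgtc gcagcgggtg ttccaactaa gcgagacatg
      241 taccagcgag gggcattttt ctacgacaaa gctcggcatt ccgaaggggc ccggcgcact
      301 gcgctcaaac gagtctgttc caccgatatc gggggccgcg aagcaaacag gcagatcttg
      361 tgaatccacg ggactatggc tgtcttagcg ggcagctgat atgttgatat tcgtccaatt
      421 aagccgcacc ttagcccccc cggatcctat gagccgagcc gtagagccgg gaaatggtat
      481 cgtgcatccc gtcgtatgtc ctatagcttt tggctggaca actccccaag ggctaagtgt
      541 gcaaattatt ggtgccagaa acttagattg atgcgaaccg agtcagtccg attgcgcctc
      601 atttgcatgg cggccatgct tgcgcccgac aacacttttt aggggatcac tgggtatacc
      661 tgcaaaggac cagatgaaca acatagtgcg tagtcaattc tacagacttc gttccctacg
      721 cccagttggc acgtgtggag ggtacaaacg ctctagtgtt tcttactgct ctggggtcac
      781 cgatctgacc ttgagtcaca actgccacat ggtgagtagc gcaatccttt acaaatccag
      841 tccggccaat actagaacat ctgtattctg agggggcctt tatgtggttt catctccttt
      901 aaggtaaacg gtccgaaaag gtactaccct gctgctgttc tcgcgggttg catggattcg
      961 ctatactgta aggagcacaa cgtctcatac aggagaatgg gcgatggggc gaaataagag
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
     1681 gctagttttc ttggtgccga ctaatttggg gtcaacgctc tcatgagacg
//
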