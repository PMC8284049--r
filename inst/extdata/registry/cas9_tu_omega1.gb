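LOCUS       cas9_tu_omega1   1730 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  cas9_tu_omega1.
ACCESSION   cas9_tu_omega1
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
     misc_feature    996..1715
                     /label="Cas9_TU"
                     /gb_role="TU"
     misc_feature    1716..1719
                     /label="OMEGA3"
                     /gb_role="fusion_site"
     misc_feature    1720..1723
                     /label="OMEGA_MID"
                     /gb_role="fusion_site"
ORIGIN
        1 aagtctccgt gttaacaata ggccacgacg aacagggtac agggtatcgt tctatgtgca
       61 aggcacaacg atctgcccgg aggaactcag tccactatga ttgaactaac gtcacacact
      121 aatggccata cgtttcctcc caccccaacg tttaaacaac acggactgac agccaactac
      181 agctccagtt tgaaccagac aaggacccta ggactacgca atgaagtttg cctgcgctta
      241 gcgtgaatgg gttccgatca ctaagtatct gccgcttccg gtacacaatt gaagatcaga
      301 attgggtttc tcgtgcaaca attcgttcca cacaaaaaag ggtcgttttt gtggaaccct
      361 tttcgcaagc ctgggcggcc tcttaaagca gtgcttatca gaccccgcaa aggcaaccag
      421 gctggtacag ccgcgtaatt gtctgtttgc aagagcaagg cgaagctgag gcaacggaaa
      481 atacgcaacc gctgctcgtg ctgtctacac gcactcacgc ccactgatcc aacgagcgct
      541 gggggaaact ggaatttata gacaactcaa tccccccagt acttgtgcat aagcggccac
      601 atagctattt cgctatcacc acagaaaagt gcttgtcgtc cagtgaacca tatgagcacg
      661 actgtgcagt gtaaccgttc gataattaga tgtaagcaat gtattattca gctttggttg
      721 gtaggcgtca tcagtagctc tagatgcttt gataatcctg tttattaaag agggttagtt
      781 tgagtccacc aggggatggt ttcaacggga ggcaggtagc tactgtatgc cggatactgg
      841 atctgttcat ttgaatccct tgctagcata tggagcttct ctgacttctg gctttctgag
      901 ggccatgctt tgcggcgtaa tgacgaatta acaggcttag tcccagggga tcctgttgtt
      961 caaatggtcc aaaatagcaa ggtctcagga gcaggaatgg gcgatggggc gaaataagag
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
     1681 gctagttttc ttggtgccga ctaatttggg gtcaactcac cattgagacc
//
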