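LOCUS       dsred_tu_alpha1  1510 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  dsred_tu_alpha1.
ACCESSION   dsred_tu_alpha1
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
     misc_feature    996..1495
                     /label="DsRed_TU"
                     /gb_role="TU"
     misc_feature    1496..1499
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    1500..1503
                     /label="ALPHA_MID"
                     /gb_role="fusion_site"
ORIGIN
        1 aagctgaagt ggtactaaca tcgggggggt attagatcgt gaaaatccaa gctctgaggc
       61 aacgagcatc tcaaatggtt atcttgttag gtacaaccgt ccacgccgag gccatattgc
      121 tcgccgactg gtgtcagtac ctttcaaggc gctgacttag cctcgcacag tccgaaacga
      181 accacatcaa cgccacctcc gtcgtagtct gcatcactta catttgttgt ctgtgctatt
      241 acgaccgacg agtcttttgc ggacaaaggg taaggatatt atcaatccga ctctccccct
      301 gatgtgagtg cccagccgtt cccgtagcca tggcctgcta acggcgttgt gcctgaacgg
      361 gtgctcgcgg ataaaaaatt agcgttatta aagcactaat ggcccaacaa tcgaaaacgg
      421 attaggatga taggtagcgg cgtagttgtg tcttatttgc cctgagcccc gtctggggcc
      481 ttggggcgaa tcccttagtc ggggttacct aggccgaaac tcgctgcgcg gcgggggaac
      541 ttggggttct ggtgcccgcc agatgcgtta ccatgttggt tagttgtttt ggacccttag
      601 cttatccgcc acaggtcaga gtaaacacaa ggtgagtcgg gacgggtggg cttggacaac
      661 tggcggtaag gcaaggaata ggtcatgctt cgtcatgtgc cggtgtgtcc aaggcctagt
      721 tataactcca tgacctttaa acaactctac taacctctcg tagcctaact ccgaaactcc
      781 tcggttctaa ccgaggaaat gtacaacgtc taattttagt ggatgatttt gcgtgggaac
      841 cacaacgttg tacctccact ggcccacgag caagcagccc aagctaatct cgagatggag
      901 ctgccttgca cttatagtta tattattcac tgtatttact taatgaaagt ccactggttt
      961 catgattcgg gcgaaataaa cgtctcacag gggagaagtc tactgggtga tgagtatcct
     1021 cataagaacc cggaattggt atatctgaaa gtggatctta ggtccatgtt ttaacagact
     1081 cataagatat aatgcctgcg gtgtagcgaa gcatacttca ccccagcatt tgcgccatgt
     1141 tggggtcaca tatttaaccc tatgaacctg cagtccggtt gggggcatcg gtgatcagag
     1201 cggttgggat cgcgtcaatc ggcgagcagt gctattctgt cgaagttgtt acgcattcag
     1261 ccgcggaacc cctctggttg ctgagtaaac gacgaggtgg tggcctgacg aaaaagatac
     1321 cccaatacaa acctggtgcc aatttcgtgc tttgtagttg tctcgtcgaa tagcaactgg
     1381 aacacacagt aagtacggtc ttatgaccca caccgatccc tcttgcctgt cgaacgacac
     1441 caagcaagct gaacgtttgg tggaccgagc taataggatg gattaggcat tcaaacgctt
     1501 acatgagacg
//
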