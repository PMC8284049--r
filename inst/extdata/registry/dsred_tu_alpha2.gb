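LOCUS       dsred_tu_alpha2  1510 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  dsred_tu_alpha2.
ACCESSION   dsred_tu_alpha2
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
     misc_feature    996..1495
                     /label="DsRed_TU"
                     /gb_role="TU"
     misc_feature    1496..1499
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    1500..1503
                     /label="OMEGA3"
                     /gb_role="fusion_site"
ORIGIN
        1 aaaactctca cagtaaacgc tttgacatcg tcagacaaag ctgtgaatga tccagcattt
       61 tacctggccg aacggttaag tgcgtagttc tacaacgggc cgatgaagtc gccagcgtca
      121 gacatttggc aaggatcgat tgcggagtat tccactcctg gctgacgttt gcaagctatt
      181 agatgggtgt gcgccaagcg aaggggtttc caacgcactc gttttaatag atatcggttt
      241 tagaagcgag acatcgatcg gaggcttaat ttttcccagg cgcgcaagct gaggacggaa
      301 tggttttact acgactaccc cccgaagcgg cacgttcgcc tacgccaaat cgcccttgcc
      361 atatttaaga aggtacccag ccggtatgta ggacaggtgg gctgttggga tccccatgcc
      421 acggcacgtt gctagatctc cgacattcac gtatgataaa tggcttgctc gcgtgcccga
      481 cgcgagatct cccaataagt ctgtggacgg ttcggcgcaa aataggtacg cgcaaaatgc
      541 cgggtcttca actccgcata tacaaatatg gtccacgaac agagcccccc gataatagtt
      601 gtgtttcgcg atctctatag ctgaatctag tgcgttaagt gagctgattt gagtacatcg
      661 acctcataag cacaaaaacc aaagggccct aatttgtctc taggagccga cttctcacct
      721 aggatggcca tgcaacgctc tgaaccctgt aggcaagagt acacactagc cacttagcga
      781 cgtcgccgaa ggagacttat ggactgcagt ctcgttttaa ggtggttttg gaagaagtga
      841 cgcctagcgc tagacgatga tcgatcggct gtgcttggca tgacgccacc gcttcattgg
      901 agaaaccggc ggtgcttctt aacaggtcat gtttagccta tgagtcctcg tgcacctgtt
      961 ccgaatgaac taccaaataa cgtctcatac aggagaagtc tactgggtga tgagtatcct
     1021 cataagaacc cggaattggt atatctgaaa gtggatctta ggtccatgtt ttaacagact
     1081 cataagatat aatgcctgcg gtgtagcgaa gcatacttca ccccagcatt tgcgccatgt
     1141 tggggtcaca tatttaaccc tatgaacctg cagtccggtt gggggcatcg gtgatcagag
     1201 cggttgggat cgcgtcaatc ggcgagcagt gctattctgt cgaagttgtt acgcattcag
     1261 ccgcggaacc cctctggttg ctgagtaaac gacgaggtgg tggcctgacg aaaaagatac
     1321 cccaatacaa acctggtgcc aatttcgtgc tttgtagttg tctcgtcgaa tagcaactgg
     1381 aacacacagt aagtacggtc ttatgaccca caccgatccc tcttgcctgt cgaacgacac
     1441 caagcaagct gaacgtttgg tggaccgagc taataggatg gattaggcat tcaaacgctc
     1501 tcatgagacg
//
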