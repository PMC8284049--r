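LOCUS       dsred_tu_omega1  1510 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  dsred_tu_omega1.
ACCESSION   dsred_tu_omega1
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
     misc_feature    996..1495
                     /label="DsRed_TU"
                     /gb_role="TU"
     misc_feature    1496..1499
                     /label="OMEGA3"
                     /gb_role="fusion_site"
     misc_feature    1500..1503
                     /label="OMEGA_MID"
                     /gb_role="fusion_site"
ORIGIN
        1 aaacgaattc gctaaggttc taacctcttt aggtgacttt tttgcactgc ccccgaagga
       61 attttaacca accatgaagc ataacacgga ctgctatggc gtagcctacg gcaaagactg
      121 cagacgaaaa gagagcgatt ccgagccgtg gagtttcgct tttactggag aaggttgttt
      181 gatttctcgc tatgaactac acttcgtcgc cggttgtcta ctcttcacac ccgtcatatc
      241 gagggaatgg agcagctacg agcagaaagc gtcgagcgaa cctttaccgg tgacgtcttt
      301 ggtcgaacgc cccggacctt agtattgccc cagcgacatg cgaaacggac acccacctga
      361 cttgaacatg atactaccgg caaacgggtg acatctaagt gcgcgaactc gcgctacggg
      421 caaggacttc gaattgaagt taccaccgca aggcttgcga cctacccact cccattcacg
      481 accggcctat aatggaatta cacggaggca ctctactcac ccaaaactaa ttgctctact
      541 cccctcggtc tggtcgcaca attatccaag aattttgact caacacagac atccagagga
      601 cggaatacct cccgacggat gtaactgtta agcagtagtt gtgcggcgtc tacacgcgat
      661 agtcgtagtt tagcaataca tccgatgatt agcagtaatc ctttcacata gtcaaaggtt
      721 gatattgtcc cccggtagac ccacacgaca ggcagcgctc cgtggaatca gcaagggcac
      781 cttgttcttg ctcccaaagg acatctctta gcccgtctgg tagcctatca ggtgtaacaa
      841 cccttgtgta cgatcaccgc agtctcgacg caatcgctgg cgcagcatcc ttattggatc
      901 tctggttcgc ttgtggggag gaggcgggca ggaggcacgc gcattacaat gactatcaat
      961 agcgggggtt taacgcgtaa ggtctcagga gcaggaagtc tactgggtga tgagtatcct
     1021 cataagaacc cggaattggt atatctgaaa gtggatctta ggtccatgtt ttaacagact
     1081 cataagatat aatgcctgcg gtgtagcgaa gcatacttca ccccagcatt tgcgccatgt
     1141 tggggtcaca tatttaaccc tatgaacctg cagtccggtt gggggcatcg gtgatcagag
     1201 cggttgggat cgcgtcaatc ggcgagcagt gctattctgt cgaagttgtt acgcattcag
     1261 ccgcggaacc cctctggttg ctgagtaaac gacgaggtgg tggcctgacg aaaaagatac
     1321 cccaatacaa acctggtgcc aatttcgtgc tttgtagttg tctcgtcgaa tagcaactgg
     1381 aacacacagt aagtacggtc ttatgaccca caccgatccc tcttgcctgt cgaacgacac
     1441 caagcaagct gaacgtttgg tggaccgagc taataggatg gattaggcat tcaaactcac
     1501 cattgagacc
//
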