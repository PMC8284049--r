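LOCUS       pUPD2            1102 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  pUPD2.
ACCESSION   pUPD2
COMMENT     gb_level: NA
COMMENT     gb_backbone: pUPD2
COMMENT     gb_marker: chloramphenicol
COMMENT     gb_provenance: NA
FEATURES             Location/Qualifiers
     misc_feature    1..820
                     /label="pUPD2_backbone"
                     /gb_role="backbone"
     misc_feature    61..660
                     /label="CmR"
                     /gb_role="marker"
     misc_feature    821..824
                     /label="UPD5"
                     /gb_role="fusion_site"
     misc_feature    832..1091
                     /label="lacZ_stuffer"
                     /gb_role="stuffer"
     misc_feature    1099..1102
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aaggcacagc ttgggagact ttaccagcac tatccatttc ggcttatggt atcccaacac
       61 tggcggacgg gcagattaag cccaaacgtg ccgtctttat ttcttgatga cattggcacc
      121 gttggtggaa tcgtcccgct ctgaatgatc cacggatcaa gatcgatgac aagctcaact
      181 cagggccctc gtgttaccct ccctctgcag tcctctagtc tccaaagcag caaatggcgc
      241 tgcggcactc taggagggcg aacctgtact caaaaggaaa agtgctgata ttgtacaatg
      301 ggcacatagt gcgcagcaaa tctgtaagaa tggtcaagca tcgacccctt cgagtctctc
      361 acctacctgc caagtaaccc tcataatggc tgaaacggca agctagatta ccgcctcata
      421 tctcgtccta ttgggatcgg tcatcttagt cacctcccgc gccaaatcga ctctattagt
      481 caactccttt tcaactgaca tgtcgggtgg actcgggtat ttggtgactc cctctacagt
      541 cagggtgcag gtgcaaggat atagaacctc ctcagttcag accgcatctg ctgacttcgg
      601 gcgattcgta cgtatcgctt attgcccaac gcgctttgcc taatggagta ctcattcgcg
      661 tcgttagtta gcaagtatct gtccgatggt agtagagagt agctgaccgg gatcacattt
      721 cctaccagca gggcacggga gatatcattg aatgagcaat atacgtttcc gatgtttgtc
      781 ggagcggcca attacaaccg cggagtggta agcttttaaa ctcgtgagac gaaaagtaac
      841 ctaaactatg ggaggaccag tccttcatct ggcaaggagg cagcgcggga gcagcgaaat
      901 acgcgggaaa cgtccgtctg catcctagcg acattagaac tggattcttt gctaggcttg
      961 aatgaagtcg atagatctcc aatttcgata gacatacccc cggtgggttc ggaacaattt
     1021 gactgcactt tttctcgtaa gttgaaaagg ctcttagcgc atgcgggttg attcgcggcc
     1081 tacaaaaaaa acgtctcagg ta
//
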