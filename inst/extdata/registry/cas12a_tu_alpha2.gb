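LOCUS       cas12a_tu_alpha2 1650 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  cas12a_tu_alpha2.
ACCESSION   cas12a_tu_alpha2
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
     misc_feature    996..1635
                     /label="Cas12a_TU"
                     /gb_role="TU"
     misc_feature    1636..1639
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    1640..1643
                     /label="OMEGA3"
                     /gb_role="fusion_site"
ORIGIN
        1 aacccttaac ttaaaagaat attagtaagt ctatagagga agcgtcaata gcttagcgtt
       61 tggattgcgc tgtccttgag caatccactc gcactctcat cactagatta gtgcctccac
      121 cgcatgtttt gacattgctc ccgaggagtc tttgcgtact ttcgagcaaa cggaatagta
      181 acatgtggta cactgacttg gagtataccc gcattcaccc cagacaagtg tactgactat
      241 tgggatccca aaaggcgtct aaagggcgga gcgcctctgg agccgtgatg gatgtcgttg
      301 gcgtgcgtcc gctggaagct gcggtctgat tgtggtcttt gtccaagccg gtagtgtccg
      361 ggctgccctt ggggataggc tgtccgatac tgcggtcacc agggaggggc gtcaggacga
      421 gccgcggaca gcgtggtacg gaagatcgcc ccgataaacg atacgagcct gtaataaacg
      481 ggattgaagg gattagggac cggggcccgc ggtcgaacgt acagatccaa taacaaacta
      541 catgatcacg gatagatctg tccgcgcgta tttctcctta tgcctatgag tcctagaagc
      601 cacaactcaa tcgagctccg cacacgcgtt gaacctgcat ctaaagacga ccttgcccgc
      661 atgaactgtg aaagtcatat gattctacaa tcggtcctac tcctccatat aatttaaagg
      721 gtggcaatga tgcagtatct taatacacac cgacccacgc acaaggggaa aacttatgtg
      781 aagctcgcgc tgacgcaatg gcgcgtatat atacggcacc ctgtacagcc tgcgcatggt
      841 gatccgacca gcttccctaa gacacccgga gaaatcgacg tgttgggagc cagtatcacg
      901 ggcgacactg gtgtcgctta aaactacctc tggcggcgaa catacacaca acctatccaa
      961 aggggtacta aagttcgaaa cgtctcatac aggagaatat cgttcagtag caggggccgc
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
     1621 ttccttcaca acaaacgctc tcatgagacg
//
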