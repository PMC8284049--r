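LOCUS       omega2           1324 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  omega2.
ACCESSION   omega2
COMMENT     gb_level: NA
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
     misc_feature    1003..1302
                     /label="lacZ_stuffer"
                     /gb_role="stuffer"
     misc_feature    1310..1313
                     /label="OMEGA3"
                     /gb_role="fusion_site"
     misc_feature    1314..1317
                     /label="VEC3"
                     /gb_role="fusion_site"
ORIGIN
        1 aacccatact gttagtgccc aaccgccggt ttggagttaa cccacggtgt agtgacaggc
       61 ctcagcaaga acagctctta tcggggcatt aaccacgttg gttcagttgg ggggcttaaa
      121 ttaggatgtc acgtaatcgg atactgcttc ccctgctgtg ccgctgagcg tagtgacgag
      181 gcgcctctct ctctgaatct ttcttcggac agaaaggcca accgatttcc gttactcata
      241 gagccccccg tctgctaatc gttcagggac gtaggctact ccgtaggaat gccgtcgctt
      301 ggagggacat acccattgta cgataatccg acgactggtg caggacgatg tgtgaggccg
      361 tgtcggaaat gtctgacgca atggccagaa tggttttgtt accgtgacta gcgtgatcgg
      421 cacccctaag agtttaatct aagaggaaca atactggtcc ttcgacacta tttaacgttc
      481 cataacgcac caagaaagta gcccgaatgc atcgtagaca cgagtttcct ggcgcatttg
      541 ttgttagagt ggctttgtat ttcttgaccc cttctatcct tagattagcg gcacttgact
      601 cacaattatt agatggagat cggcggaggc acagccgtag agtcttggcg tgtgttcgca
      661 gccgtgcaat gtccctttcc catcgtggta aagagtaagg accacttcgc gcatcccgtt
      721 tatgagcagg gatatcctcc ctgacggtgt ccccaggacg caagagtgga cgttcgcgct
      781 aagcactgcc ttactctctg gagggcatct taaacttgtt aaagcgcctc agctagttca
      841 tagacccata gggtctgact tggtagcgca cgtggatatg ctactgcttt ggaggtttcc
      901 cgattacacg tcagcgaagg ccatggagcg aaacgcagta tagagtgatt ggtaccgaat
      961 aatcctaggc tatttcaaaa ggtctcacca tcaggtgaga cgaagggatt taatcaagcc
     1021 tgggaacgtc caggtggcat acgaggccgg aaaaagcctc ccgcgtcccg tcaaattgat
     1081 atgatcatgg ccccgccctt tggcctatat taccggcgac ttcacgtacc tccaacctgt
     1141 agttcctagt cgatctaaca atacgcccgt actctaggtg gtgtgtgtcc ttggatgata
     1201 gattagcata agggctgccc gcagcaggca ttgaggtagc atggggcacc tcagagcaaa
     1261 cgttatctca tcgtggaatc gacgcaccat cggaaccctc aacgtctcac tcacgcttga
     1321 gacc
//
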