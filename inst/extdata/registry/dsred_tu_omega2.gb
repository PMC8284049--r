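LOCUS       dsred_tu_omega2  1510 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  dsred_tu_omega2.
ACCESSION   dsred_tu_omega2
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
     misc_feature    996..1495
                     /label="DsRed_TU"
                     /gb_role="TU"
     misc_feature    1496..1499
                     /label="OMEGA3"
                     /gb_role="fusion_site"
     misc_feature    1500..1503
                     /label="VEC3"
                     /gb_role="fusion_site"
ORIGIN
        1 aaacgagtat accgccacac agctgaggaa ccagcagttc gaccatctaa gtacgtttga
       61 ccagggtcga tgtccttctg tattgggaca gcggctgcca tgtctagttc tgcacctgag
      121 ggctacatag caagtgttaa taatgacagt aatccttggt gtctttccct aagcaacctt
      181 ttcccttgtt caatgtggat ggtcagagac aggatagagg aattcctcga aaacaggact
      241 ttagttacgt atcaccatac ttgcggaaat gcctgttccg cgtcgcgtta tctcagaaaa
      301 agggagtagc ccctatgcat ataagatttg cccctgagca gctattagat taccccaccg
      361 aggccagatc caaaactacg cttctctcac gaggcacttg ctatgactct aggcgcctcc
      421 atctacaact gtaccccgga ccgtgaggtg cgcatttaat caatggctaa ccgaagttag
      481 tgggccccat ggaatgacat ccctattgga acaccgggcg atgaactcag ttttcctagg
      541 gcgcacagga tggttttact ccgacgtcgt ggccggggtt acgaaccgta gctatcatgg
      601 tatccaattg ggcgtgcaaa agttggcacc ggtcttgcca cgtgttggta tagatctgaa
      661 attaccatag tgcgacccgt cggtgggtct gtggccatgc ggggtgcaac atgatagaac
      721 gggtcgtaaa ttacgaacta tggaagctga acttccgtaa gagtcctccc ggatgataca
      781 aatagaggtc caggtgcgaa agaactcatc caactggcag agagcgtcaa aagcaattct
      841 gagtggttat attacactat aataagcacc tttattagta gtgctagtaa cgaagctatg
      901 tttcttcgat atcaacatta cttgcctaaa acctgttctg tttagttacg caagggttaa
      961 cccgtcctat tctgctgtaa ggtctcacca tcaggaagtc tactgggtga tgagtatcct
     1021 cataagaacc cggaattggt atatctgaaa gtggatctta ggtccatgtt ttaacagact
     1081 cataagatat aatgcctgcg gtgtagcgaa gcatacttca ccccagcatt tgcgccatgt
     1141 tggggtcaca tatttaaccc tatgaacctg cagtccggtt gggggcatcg gtgatcagag
     1201 cggttgggat cgcgtcaatc ggcgagcagt gctattctgt cgaagttgtt acgcattcag
     1261 ccgcggaacc cctctggttg ctgagtaaac gacgaggtgg tggcctgacg aaaaagatac
     1321 cccaatacaa acctggtgcc aatttcgtgc tttgtagttg tctcgtcgaa tagcaactgg
     1381 aacacacagt aagtacggtc ttatgaccca caccgatccc tcttgcctgt cgaacgacac
     1441 caagcaagct gaacgtttgg tggaccgagc taataggatg gattaggcat tcaaactcac
     1501 gcttgagacc
//
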