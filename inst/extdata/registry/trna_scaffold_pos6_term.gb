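LOCUS       trna_scaffold_po 1034 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_pos6_term.
ACCESSION   trna_scaffold_pos6_term
COMMENT     gb_level: minus1
COMMENT     gb_backbone: level_minus1
COMMENT     gb_marker: ampicillin
COMMENT     gb_provenance: NA
FEATURES             Location/Qualifiers
     misc_feature    1..760
                     /label="level_minus1_backbone"
                     /gb_role="backbone"
     misc_feature    61..660
                     /label="AmpR"
                     /gb_role="marker"
     misc_feature    768..771
                     /label="UPD5"
                     /gb_role="fusion_site"
     misc_feature    779..855
                     /label="pre_tRNA_pos6"
                     /gb_role="tRNA"
     misc_feature    779..782
                     /label="POS5"
                     /gb_role="fusion_site"
     misc_feature    852..855
                     /label="TRNA_SPACER"
                     /gb_role="fusion_site"
     misc_feature    930..1005
                     /label="sgRNA_scaffold"
                     /gb_role="scaffold"
     misc_feature    930..933
                     /label="GUIDE_SCAFFOLD"
                     /gb_role="fusion_site"
     misc_feature    1006..1012
                     /label="PolIII_terminator"
                     /gb_role="terminator"
     misc_feature    1013..1016
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    1024..1027
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aagaattaag atcgctaggc gtatcaaccg acgccatgat ggatgacccc ccagcctaac
       61 agttggacta agacatattt tttccgagta cgtcctctcg atctgaagca tcccttcaat
      121 ataaacagcc cgaacctggt tcagcgcacc tgtctaaagt taccggggtt acaccaggag
      181 tatactgctt ggaggtggta ccgtcactgt agatagctgc gaaattttag cgaacccgga
      241 ggcatacgag tatggaacgt gcaacgagat attccttgca taagttccca cacccatgca
      301 cggaactcac aagttaacac aacgtaaagc tacccggaac atacagaaga ttctgcgaca
      361 tataaatcgt taaagtcgat tacctacact gcaagaccta ggccagtatt cagaggctgg
      421 attcttacag cggagtcgac gagcggtccg aattgctcat gtaaaataat aggtcaatat
      481 tgattaacta atcactcccc gcccaactag gccgggtgcg taaaatagtt ttgaaccacc
      541 gatcagccga acgtgcttca gtcctagcag acgacgggcg ctggaccggg agcagtggaa
      601 caccgaatca ttcaagagtc ggcagcgata aagataaagg tggaaatggg cagtggacgc
      661 ttcttccgct atagcaaccc gggccgctcg ttgtgaacgt ttcaaccgat agagcctagt
      721 tgaagatccg cgttcatatg atatatttgc atccttgtaa cgtctcactc gggtctcatg
      781 gaaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaagcaagc acgacgatgt ctcgtttcat ggaagtatgt
      901 aaacctctcc ctatctttac aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaact tgaaaaagtg gcaccgagtc ggtgcttttt ttcgcttgag
     1021 accggtatga gacg
//
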