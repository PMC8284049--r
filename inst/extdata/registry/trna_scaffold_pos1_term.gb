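LOCUS       trna_scaffold_po 1034 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_pos1_term.
ACCESSION   trna_scaffold_pos1_term
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
                     /label="pre_tRNA_pos1"
                     /gb_role="tRNA"
     misc_feature    779..782
                     /label="POS0"
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
        1 aactgggacc ggtatggtac gcgggaacta caaaatcatc aaatcgtttt ttgggaaaga
       61 tggtgcgtaa aatggaaccg ccaccaattc taaaaggcgc attggcctga cgcttgctta
      121 ggcaccaact accactcata ttgattccgg cgacctctct aagcgcgacg gtgccaacta
      181 tctaccagtg cagatgggtg aaggaggtag atggacagtc ttaagctacg tcacagatca
      241 gctgtgttat gcggcgttac tcaccgttcg agtaccagcc ggtggctcca tacgctagtt
      301 atagttccag aagatcccgt gatctctcag ctgggtgtgg atgtaactgt tggctaaatt
      361 accataggct gtcgcaccat tagataaggt gatccgcaca ggactgatag cgacattcta
      421 tagctggctt aactaaaatg gtgtctctcg gaagtccctg ttgtgccgcg aaactcagct
      481 ttgttatgac tttagtggtt tgctcgcgtt tggtcgcgca cgaccctggc cacgtgtagc
      541 ctactcgtca tgagagtgct catagctctc tttggttgag ggagctggcc ctcagtctaa
      601 catcattagt cccgcgctga tagtttcgag tatgagaaaa tacgaggggt gctaacgggt
      661 aagagtggct tagaagaatt gttgtacaaa tcgcgatctc ctctaaccag attgtctgaa
      721 catagatggg tatacttaag cgcgatacat tactgcaaaa cgtctcactc gggtctcaca
      781 ccaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaacgcttt atttcaacag tgagatcgcc aaggcttatt
      901 atggctacca cgttggaaag aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaact tgaaaaagtg gcaccgagtc ggtgcttttt ttcgcttgag
     1021 accggtatga gacg
//
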