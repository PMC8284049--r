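LOCUS       trna_scaffold_po 1034 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_pos4_term.
ACCESSION   trna_scaffold_pos4_term
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
                     /label="pre_tRNA_pos4"
                     /gb_role="tRNA"
     misc_feature    779..782
                     /label="POS3"
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
        1 aaaagcgcta ggatagtccc gcctccgtta ggtgtaacaa cggatggaca cggtatcagg
       61 tcttgacaga agacaatgga ttctagttga ggttggttgc tgctcgcagc aagcaatcag
      121 caccgctccg tgtccgtcta ggccacacgc gaaatccgtt ggccccctgt gcgaccatgt
      181 gcgtgaacgc tattaaagtt ccccctctgt tttgtagaca aaagcgtgcc cacggattca
      241 gtgcttgcca ccctgaatcc agacttcgag tactccccat aaaaagatta ataggcccgt
      301 aggtgaaatg tggtatatgt taacttagtt accgcgccgt ccccgatctg gtacgggatt
      361 tttgccaagc ttgttccgtc ccggcctcgg tttctctctc cgtctggccg attaacggag
      421 aagagaaaca agtagaggga caaggctatg tgaagagtgc tgtaacttca acttgcgcag
      481 agtctgaatc cgtcaaagtg tgaaaatcta cattacacgg tagccttgga gagtattagt
      541 ccatggacaa agatactatg agcttttagc ggtaaggtgt cccgtttagg ttaatgatta
      601 tggaggcaca gagcgctggg aggagccgcg gctcgaagaa tagccgcaca agaaccagcc
      661 acctacccga cccggcggac tcggaaccca accattccat agtattcgca ctcgggtgac
      721 aggcttgcca ggggcgctta cttaacagac caaccgtaaa cgtctcactc gggtctcatt
      781 acaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaacccagg tcagtattcc tcaaccaata aacgcctgaa
      901 cactagttgt cccgtttctt aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaact tgaaaaagtg gcaccgagtc ggtgcttttt ttcgcttgag
     1021 accggtatga gacg
//
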