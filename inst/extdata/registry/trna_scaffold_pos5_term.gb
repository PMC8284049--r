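LOCUS       trna_scaffold_po 1034 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_pos5_term.
ACCESSION   trna_scaffold_pos5_term
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
                     /label="pre_tRNA_pos5"
                     /gb_role="tRNA"
     misc_feature    779..782
                     /label="POS4"
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
        1 aaccatggcg atattggaga gaaaggctac cgaataactg agaacgagac tatggcacag
       61 ctactggcgc caacagctcg tagatagaac gcctcggcga ccatagttga gtaggctctc
      121 tgtgaacagt tacgcgcgcc cgccgtaggc tgtagaccct ccgttgactt actggaagcc
      181 cacgaacggc aagacgaccg attcattggt ttactctatt acgttggatg ggctccattc
      241 atgcatgaaa ctctgtccag tgctaagtaa gtggggatct tgcatcataa tctttatctc
      301 cttaactgta gactccacta ctttgtagcg atcaaagatc ctgtgcgcat agaatatcgt
      361 taaaggtagc ataggctccg atacaatgac agtatggcga agctactcgc cttcacacct
      421 cgaccgacac cttctccgct gcaagtggag ccaacctgtc tagggacaag gtactttcca
      481 tgggagcgca tcctcaaggt ggacgaacct catcatggca acataacccc tgtacctcac
      541 aacgctcttt actcggatgc cagttcgaga aatcatttac cgtccattag cgggtttatc
      601 gtccaaccta agagtgttag ttctcgctga ctattacggg agagaaggga tagcctctgt
      661 atgctgtaca gtcaccatac ggccatactg caggaatgca attcctgtat gtcccactga
      721 agttgaatct attgtcgatg gtcagatgac atgtaccaaa cgtctcactc gggtctcaca
      781 gcaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaacgacgg ggagcgtggt aagaccaata aggactggca
      901 tttgaaggcc atcgtctaaa aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaact tgaaaaagtg gcaccgagtc ggtgcttttt ttcgcttgag
     1021 accggtatga gacg
//
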