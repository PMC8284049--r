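LOCUS       trna_scaffold_po 1034 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_pos3_term.
ACCESSION   trna_scaffold_pos3_term
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
                     /label="pre_tRNA_pos3"
                     /gb_role="tRNA"
     misc_feature    779..782
                     /label="POS2"
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
        1 aaaaagtccg actagaccgg tacatgtgtc ccccctaact aaatgttaac tcgccaggtg
       61 cgctgctagt tagtgggtgt cctcgataat accagcatca aaaggtgtga taatacatcc
      121 aggtctggtt cgaaacgctc agcgccaata ccatacgcta tgggtactcc cagcccattt
      181 caccctttgc gttcgtaccg acctccaatc ggtcatccga attattaccg tctgctcatt
      241 gaggccccta ggtacgtggg tcacaggacc gtacgtacgt ggcgattgcg tcgaagaata
      301 catctgtttc ctaatctttc gacctgctac tggatacagg tatcttcaca tgtacgctta
      361 gcaccgcggc actgcctgaa cccggggccg aaccgtatgc cctcctaacc cagcagtcgg
      421 atcgttcgat cgacgattaa gaaccgtttc tttaaagacg ggatgtgagg gggttttatc
      481 agcaatcctc cccgtacata aaagtgtccc ataagagaac gggatcaaac cgtaaactct
      541 tgatgagcaa tctgtcggcg tgggaaactg acggacgaac agactcagta atagtgtaaa
      601 gatgtttttc ggtccgaaag ccacaccatc tgtgcccgaa tatacacaca tactcgtcac
      661 gcgtagactc gcttaccaac ccgtagactt ggggaggctg cacacacgga accgaggctg
      721 gctagtaatt gaccagaact gaattttcgt cccatacaaa cgtctcactc gggtctcaac
      781 taaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaagttagg agctacatta agtcatttat cacactgatt
      901 aactggtgcc ccatgtatct aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaact tgaaaaagtg gcaccgagtc ggtgcttttt ttcgcttgag
     1021 accggtatga gacg
//
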