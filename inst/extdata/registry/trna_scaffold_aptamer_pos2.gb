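LOCUS       trna_scaffold_ap 1046 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_aptamer_pos2.
ACCESSION   trna_scaffold_aptamer_pos2
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
                     /label="pre_tRNA_pos2"
                     /gb_role="tRNA"
     misc_feature    779..782
                     /label="POS1"
                     /gb_role="fusion_site"
     misc_feature    852..855
                     /label="TRNA_SPACER"
                     /gb_role="fusion_site"
     misc_feature    930..1024
                     /label="sgRNA_scaffold_MS2"
                     /gb_role="scaffold"
     misc_feature    930..933
                     /label="GUIDE_SCAFFOLD"
                     /gb_role="fusion_site"
     misc_feature    978..996
                     /label="MS2_aptamer"
                     /gb_role="misc"
     misc_feature    1025..1028
                     /label="POS2"
                     /gb_role="fusion_site"
     misc_feature    1036..1039
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aaaatctatc tgcatttatg ccaaggcgaa ggcaaccgca aattcttgtc atatgggata
       61 gtattcgcgc attcaggtgc tatccccgtc ggtcgtatgg gacctcgcta gaaagcatgt
      121 aacggttcta ctgcttgatg gaacgcgtgt atctccgacg aacgttccct ccatgactcc
      181 gcagggagta cattagagca agccacatcg taatgccaga tctcttcggt tggacctgtg
      241 tcccaggaac aactatcaat actccaacca atcctgagtg ccatattatt ccccaaagtt
      301 gatgtcattg cccgataccg agtcccgtgg tatagtcact gcgatacgat atagaacagt
      361 gcttctaccg tcagtaatca gagctccggt tctaaaatgg ttgattatcg cagggaaaat
      421 acaaacatgt cttgtacgcc taagttaccc agcgtattga atatccttga gcaggcccag
      481 gccgatcgcg aatccaatct taactagcca agcatttatc ggataccccc gcggtggacc
      541 atatggagag cttggcaatt tgtatatacg cattatccgt acgcagggct tagacaacca
      601 catggcgtga acaccaagaa cactaccgtc gagttcctgc gcgtgccccg tacggagcag
      661 cacccaggag gctttaatgg cgttaaggcc ctatgacgcg gtgtgcgctg aacttactac
      721 cgccctcgag tgcttcacaa gtttctgggt aattcaccaa cgtctcactc gggtctcagc
      781 aaaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaaactatt tacacgggaa ataattcgaa aggactgacc
      901 cctagataac gaataatccg aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaaca tgaggatcac ccatgtactt gaaaaagtgg caccgagtcg
     1021 gtgcactatg agaccggtat gagacg
//
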