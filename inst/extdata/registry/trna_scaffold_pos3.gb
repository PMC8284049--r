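LOCUS       trna_scaffold_po 1027 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_pos3.
ACCESSION   trna_scaffold_pos3
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
     misc_feature    1006..1009
                     /label="POS3"
                     /gb_role="fusion_site"
     misc_feature    1017..1020
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aaaaattcaa ggctttctcc ttgtgtgtat ggatcgaccg agagtgtctc atactagaag
       61 gtattcgcat ccacccagtc cgactgaact tcgcgcatgg tttcaaattt tattcccata
      121 acagagcatt tgggtacaca cgctcgatgg tacacctagt caacatgggg ttatgcgatc
      181 ggtaaagact ccctagtcag cgcacgatat aggtataagc ctacgttatc catacgcaag
      241 gcgcttgaac aatgctgctg atacgttttg gctagttcat tcgagggggg gccatgtgat
      301 cggagtgtgt tactgaagcc tcctgttcgg gtaccaggtc acgccggaac actttagtgg
      361 agcagctaac tcatacattc cgcgctaatg gttgacaccg ctagtagcct cagggccctg
      421 gctaaggatg tcggctgaca tccgcgaact atttaagacc cgtcgcaagg acgtgtagac
      481 cagcctcctt attcttaata cccgtactac aatggacacc attacgaatg cgtgtaccag
      541 agcgctgtac caaccaacgg cccatacatg aggggacaga ccgtccgtag cgcctcatca
      601 tgtatgtgcc aaatccggct ttcttatcac cctatttgtg ttattcacct tcacacaccc
      661 tgcgtaaggt gctaggttag cctcgaaatg tcgcgcagcc tgtggcgaga cataagagat
      721 gcgttgatca acgtgcgcgt tcacccattg cggattagaa cgtctcactc gggtctcaac
      781 taaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaatagacc aggcgtggag gccggtttcg atactgatgt
      901 cccatagaaa agattcttca aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaact tgaaaaagtg gcaccgagtc ggtgcttact gagaccggta
     1021 tgagacg
//
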