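LOCUS       trna_scaffold_po 1027 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_pos2.
ACCESSION   trna_scaffold_pos2
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
     misc_feature    930..1005
                     /label="sgRNA_scaffold"
                     /gb_role="scaffold"
     misc_feature    930..933
                     /label="GUIDE_SCAFFOLD"
                     /gb_role="fusion_site"
     misc_feature    1006..1009
                     /label="POS2"
                     /gb_role="fusion_site"
     misc_feature    1017..1020
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aacagatggg cgtaccatct caacccccca tcatcaaatg tcgagctatc gtaaataatt
       61 accaatccgg acggtccaat ctagcgccat ctacgacgaa gcttggctgc tctaaccctc
      121 aaagcgagcc acctttgcag gatacatagc ttgacttggt accgatggta ttctccgggt
      181 agggagcgcg atacctgagc gttcttgtcc tgtgacgttt ccctgccggc aggactcact
      241 gcgaatttgt gttacatctg cggtggggtc aaaatggctg aatctcgggg attaccgagt
      301 atgataaatt actgaatatg gaggggagat cggcctgtcc aaggtcagcg cgtatccgtg
      361 gtggttacga tgttgtgtat agcctggagc aggtgaagta ctcacggcat aacggtcctg
      421 ctcggtacct cgccggaatc ggaagaactg tatcagagag aggttctgtc caagtaatgg
      481 tacttgggcc cctgtaataa cacagcgtaa aaatggggct ctactgattg ggaccgacta
      541 tggtctattt tagcgtcgtg tttacggata tatttataga ccatccactt agagcgcact
      601 aacagccccg gatactggtg ctggtcatta atgtaggcac cagctgtgtt tgataataga
      661 agtgggaact gctcactttg taagccgatg ctagggtcct tccgccaaga gcgcaagcca
      721 atctgtagct gaatctgcgc aggaagtttt gaatgtctaa cgtctcactc gggtctcagc
      781 aaaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaatggagt agccggagca ttgagctcat gactactcct
      901 gacagggacg gtttagtccg aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaact tgaaaaagtg gcaccgagtc ggtgcactat gagaccggta
     1021 tgagacg
//
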