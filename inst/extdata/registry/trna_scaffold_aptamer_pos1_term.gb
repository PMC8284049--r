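LOCUS       trna_scaffold_ap 1053 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_aptamer_pos1_term.
ACCESSION   trna_scaffold_aptamer_pos1_term
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
     misc_feature    930..1024
                     /label="sgRNA_scaffold_MS2"
                     /gb_role="scaffold"
     misc_feature    930..933
                     /label="GUIDE_SCAFFOLD"
                     /gb_role="fusion_site"
     misc_feature    978..996
                     /label="MS2_aptamer"
                     /gb_role="misc"
     misc_feature    1025..1031
                     /label="PolIII_terminator"
                     /gb_role="terminator"
     misc_feature    1032..1035
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    1043..1046
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aacccgccgc aggctcaagt ccacagcgcc tgtctcaatc ctagcaagcg aggtggagta
       61 ctagaagcac aaaatctgaa atcctctttt tgggtgtcct atctcgcaca aaccggcagg
      121 agaagccaag gctccctgaa aaggctccgt aggaatccgt tgtcgacaac tgctgcggtg
      181 ttgcctcgtt tcataaatgc gtcgctagtt ctgtgttgga tatattcgta gggcgggtcg
      241 gtgaccaggc ttagtggtga aacgaccaag aacggagtga gatgatggcg cgctaacaat
      301 cggcgtttcg ccggcgccct cttgcggatc ctatacatgt ggttcacaga cggtcacggt
      361 gaggttcatg gagcctcggc acaaagggtt taacttattc gctagcatgc ggtatagaac
      421 caagacgttg cgcaccgatt gccaggttag atggaccaga atagcaccgt tttggtgaga
      481 ttcgcgtatt tatgactgcg acggattaaa gagagtcagt cctcatcgga aacggccctt
      541 cggaccaggt cgatttcccc cacatcatct cggcaggtgg gcaaatggag ctgacatatc
      601 ctaagttgtg agcaccgacg tgccctcgcc tcgatggatt tacgagcgct tgtccaagcc
      661 cacggcctct gagcctcgcg gttaagggcc ggtccgttct gcgattattt cagcgaccct
      721 accacgcgca taaaagagtg tcgggagtaa agggtagcaa cgtctcactc gggtctcaca
      781 ccaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaagttcaa tccggggggg cacgacgggc cgaaccgcat
      901 gacaactcac gattaatgcc aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaaca tgaggatcac ccatgtactt gaaaaagtgg caccgagtcg
     1021 gtgctttttt tcgcttgaga ccggtatgag acg
//
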