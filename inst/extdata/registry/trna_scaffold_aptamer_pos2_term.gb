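LOCUS       trna_scaffold_ap 1053 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_aptamer_pos2_term.
ACCESSION   trna_scaffold_aptamer_pos2_term
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
        1 aaaaatcgac aacaccggaa tgactagtaa aataatccgc ttgacgcaaa tctcatccgg
       61 ttcacccctg ctgtgggcta ggtagaatag cgcgacgctg gttaacgata cactattata
      121 gtacctgctt caaagcctag gaaacaactg gagaaaaaga gccttgcgta ctacttaaca
      181 cgcaatgggc caactccgtg aagcgtctaa gaccagacgc cgcctgtccg gagtcaatga
      241 gagctatgaa aggtgtccca aagtctcaag cagagcagta gagccatgac ggtagcacgt
      301 accccgctcg aacattcgcg ggtctaaact gtacgcacta gcctataact taagtgcgcg
      361 ctttcatacc gtggagttgt tgacttcgcc tatcaatctc cgcggcagca gtgaaacgat
      421 ggggagtgaa atgagaatgt gcggtcgagt cggaatcgtc aggggtggga tacagcgcgt
      481 tcatgcgact agttgcctgg gaagtgacat tgcagggttt ttcgataaca aacgtggatc
      541 cttagaacca atcgtggtat gggtcggcgc taacatatag acaggatgtg cgagcattca
      601 ccatatcccg gaagtagcgt ctacaagtga atcttcagcc gcagatcggg gttaccgcgt
      661 aggactgccc tagaagcaac ctagtcggta cggacacgtt tcttgcgggt gggagtagtc
      721 atacccatcc ctgacatcac ccggaattca atagttagaa cgtctcactc gggtctcagc
      781 aaaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaaaatggt ctaacggtta gccgggaaaa agttcagtgt
      901 tgcacgcggt accaaagcct aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaaca tgaggatcac ccatgtactt gaaaaagtgg caccgagtcg
     1021 gtgctttttt tcgcttgaga ccggtatgag acg
//
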