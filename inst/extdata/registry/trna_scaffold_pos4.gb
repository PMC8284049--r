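LOCUS       trna_scaffold_po 1027 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_pos4.
ACCESSION   trna_scaffold_pos4
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
     misc_feature    1006..1009
                     /label="POS4"
                     /gb_role="fusion_site"
     misc_feature    1017..1020
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aaagcatagt taactccacg cggcttgttt tcgctactaa gatcgctttg ttcacgcggc
       61 attggttttt gggtcggact gtacgtccac taaggggttc ggtattatag taacactaat
      121 cgaacttcgc ggacacctgg aatcccaaaa tttcccgagg tcatgagaga gccctttcgg
      181 accctaagtt aagcgtcacg aacgctcggg agcctctgaa gtcttatttg ctcgcacagt
      241 acagcgagtt cccaaggttg gctgaagtcc tgctggcgga ccgaaggtcc gacgatagac
      301 tgtcctgtaa ggtgtataag tgtctaaccc acccaacgta ccaatagaat ggcctagctt
      361 gaggtagtag taactctcga acagatacac acggctcaaa tcacaggtaa ggggcggaag
      421 gccgcgtgaa acccatgttt attagaagtt atacttttat tttgactctg ttatggccga
      481 atccacttac aactggctcg tccatacgaa ggtcgcctag tagttattcg acggttacga
      541 atgtcaaata tgttctctgg taactaggtt ccaatagaag ggtaacttag aggggtacag
      601 actaggttgc cggcaccgca caccttggta catgatacag atccccagac ttcatcgtaa
      661 cccatgttca atactatatg tttctgaaac gcgatggata atcagtaagt cacgctgcaa
      721 acatactccc gatatcacgc acgcgaccat cacgtacaaa cgtctcactc gggtctcatt
      781 acaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaagagaac tctccacggt attcggccag agtcaatgcc
      901 cgtggacgcg acgacggatc aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaact tgaaaaagtg gcaccgagtc ggtgccagct gagaccggta
     1021 tgagacg
//
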