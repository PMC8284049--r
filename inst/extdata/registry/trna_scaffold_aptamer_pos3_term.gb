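LOCUS       trna_scaffold_ap 1053 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_aptamer_pos3_term.
ACCESSION   trna_scaffold_aptamer_pos3_term
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
        1 aacgatatcc gtccgtagaa tcccgatctg tgcatagacg cgataaaaca ccttcaaaac
       61 ggatccatgc gtgttgtggc taatgctaga gaggtaatcg tcaaacaaac tgttgatctt
      121 catatatttg aagtgccttg acctcactct tagcagattg tagatggtct ggaaatgtaa
      181 ttcagggtcc gttgccattt ctatcttagg cttctgtatc tcggacggag ctctcagagc
      241 cacgaacgag tcccacgaga tgttgactta tcttaggatt cggtgggcca tgaaaatcga
      301 gctttgcgca ccggacctgg ttagcgtgct aatgagcgct accacactca ctctattacc
      361 cgaatgcttg taatgtaact acagattccc agcggtctga agttgaacgt actacttccc
      421 attaacagca aaccggatga cagcggcgac ggggtatgct tgtaacagag ttatgaacta
      481 taaccggctt tgcaaggata atttacggaa gtgataagcg gtccaatggg tggagggaag
      541 tcggtgggag ccaatagcac cgcatttctg tcagcattcg aaaaattgaa gaatggccac
      601 agtttatcct cttagggtag gcgatgcatc accttgcgaa tagtttagtg catgagcccc
      661 attcgcggcc ggcaagttcg aagtggttgg tttatctaga tactagccgt gcaacgtcca
      721 gcgataacta gaatggaggc cactagcgag ataacgtgaa cgtctcactc gggtctcaac
      781 taaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaaagctgt gccgcaacca accattgagg gtgccgcaca
      901 accattactt catgtcgccc aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaaca tgaggatcac ccatgtactt gaaaaagtgg caccgagtcg
     1021 gtgctttttt tcgcttgaga ccggtatgag acg
//
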