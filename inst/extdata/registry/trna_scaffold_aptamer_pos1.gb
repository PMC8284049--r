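LOCUS       trna_scaffold_ap 1046 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_aptamer_pos1.
ACCESSION   trna_scaffold_aptamer_pos1
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
     misc_feature    1025..1028
                     /label="POS1"
                     /gb_role="fusion_site"
     misc_feature    1036..1039
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aagagtagtc gcttgggctc gtctaaaacc gcatgcagta aaagagactt gttaagcgct
       61 actgagatag acaagaaacg ccgatcgtta cgcgtatcta gtttgagggc tacgcagacg
      121 attgcgtatt aggtaagccg acaaagccgg agtgggcagt atgaacaaca gacgcccgca
      181 aggttcgcat acggcaagag tccgcaacgt acgttccctg attttagtag tcaagttgtt
      241 ttcggatcgg gcgcgagttc cagagtacat gtccaggaga tgcctcttac ataatcaatg
      301 ttggcgtgcg aagtagcgca cgcagcgttg atgtaacgat gcggccatgg cgctacttat
      361 gtcggccagg cttatgctta gctagtccac tcgagtgtcc aagaataaag tgcatcgctg
      421 cggctccaaa tctatggccg gtagatcgtt ctgagatcgc ggaccatgtt tgaattgcta
      481 acccccatta aatttggcgg ccatgactgg aactgtcaaa tttagtaaca ccttctctct
      541 ccttggcttg cagagggcgg aggagaacaa gccatttgga gtagcgtaaa ctcctgtaat
      601 gagctccgtg aggcggctgt atgtgaagcg gggcgcaaac ccaaatgcac agctgcgtac
      661 cgcgcttatt ctgtgtaacc gtcaatgaag ggatcgctta acttaggtca ttataatctg
      721 ttagcaatgg gcaaatcgta aagggtcgta acctattaaa cgtctcactc gggtctcaca
      781 ccaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaacaccac atttgagcga tcacaaacca cgcaatacca
      901 cgcatttatg caaggctgta aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaaca tgaggatcac ccatgtactt gaaaaagtgg caccgagtcg
     1021 gtgcgcaatg agaccggtat gagacg
//
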