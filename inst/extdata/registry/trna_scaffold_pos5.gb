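LOCUS       trna_scaffold_po 1027 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_pos5.
ACCESSION   trna_scaffold_pos5
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
     misc_feature    1006..1009
                     /label="POS5"
                     /gb_role="fusion_site"
     misc_feature    1017..1020
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aacattcgca gtgtagctat ccccgggtaa gcctgtacat cagcgctata tgacaccggt
       61 actattcgat aggaaattta cgacatggga ccgaaaagga gcaggtgggt ataacggagt
      121 gtccacgtga attcctgtga ctgttttaga tgctgagtta gcaacaaatt tcggacccca
      181 agtgtaaaga tgccatttaa gacccgatgc aggcggcgaa tcatccccgc aaccgctaca
      241 agagcttaat cgggcaaacg aaggcgccac gctctgtggg tagtgttaga tggcggttgc
      301 gctatcgatc gacctgcccc acctgacttt tcgagcactg acaggcagta gcacccaata
      361 atcgaacact ctagttggac cgacgcccgg attagagctc agtattagtt tgttcactac
      421 gactaagcaa gcccagggcg agctgtcgcc attgacgtat tatattaaat ggcgcattga
      481 ttccttgaat caatcggatg ttatctcctc ttcgagggcc ttcgcgcggg acttggtaga
      541 atcgggccgt cagtgtatca cacaaggggc ctttttacta agcgcccaca tgtcgcctat
      601 ctccaggcga atattcagac taacacttta ctgagcgaaa ctacttcctc aagaatcgct
      661 cggctatttc ctgaatagcc agataggtgt gctcttctcg tactattcaa tacgtttacc
      721 catacgtagt ttgcacaaca gagcgcaagt accgaagtaa cgtctcactc gggtctcaca
      781 gcaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaatggtcc gagttttagt ccacgctatt ctctatagct
      901 tggaagtctt cagcatgacc aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaact tgaaaaagtg gcaccgagtc ggtgctggat gagaccggta
     1021 tgagacg
//
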