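LOCUS       trna_scaffold_po 1034 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_pos2_term.
ACCESSION   trna_scaffold_pos2_term
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
        1 aaaaaccgat cccgttaggc cgaccaggcg gattttgcat ttcacgtcgt atgatgatca
       61 ccgacttatt aacaaacgcg actttagact taccggcgcc gtcgttagaa gtgtccttcg
      121 aaacgcaaca gtttcgtgca acgatcacaa cgcccatccg atccattcga tgtgccgaat
      181 tacgacatgc aatcaaaaac agaagtccgg acgtggattg tctaatggaa taccaagcca
      241 ggtagaccag cgcctaatat caggcacata cgagcatggg gccgttagac gaaccccggc
      301 atgattgtgt atctatccgc gctctgatcc ccaagcatcc aatgaaggca gctagctgtt
      361 tacgggtgcg ttgtgctgtc tgggcaaacg caactcttca aatcagcggc gaagggtgtg
      421 catgcccaca accatatcgc gctactacgc tgggcagact tcctgtcaac cctgagctct
      481 gtacatcgtg aggtagaaga atcgtgtaca gtcctgacct cccggcccgc tctagaaaaa
      541 cccgcatttc cgcgaatcgc taattcacac gtgcggtcgg ctagttgtac tgcaccctga
      601 aaactccagt cgccacaagc gggggattct attacaatga tctgaagatg cttcagcatg
      661 atcaaatacc acctaacacc cttggttgtc ggtccagttc gcttctgcct agcggcgtat
      721 agtaaccgac agcgccaatg atacgaggca gcccgatgaa cgtctcactc gggtctcagc
      781 aaaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaagtgctt cacactgttg tcaatgctct gatcctcttc
      901 tgttcagtac agtctaagac aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaact tgaaaaagtg gcaccgagtc ggtgcttttt ttcgcttgag
     1021 accggtatga gacg
//
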