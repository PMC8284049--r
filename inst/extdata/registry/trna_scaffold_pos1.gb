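LOCUS       trna_scaffold_po 1027 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  trna_scaffold_pos1.
ACCESSION   trna_scaffold_pos1
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
     misc_feature    930..1005
                     /label="sgRNA_scaffold"
                     /gb_role="scaffold"
     misc_feature    930..933
                     /label="GUIDE_SCAFFOLD"
                     /gb_role="fusion_site"
     misc_feature    1006..1009
                     /label="POS1"
                     /gb_role="fusion_site"
     misc_feature    1017..1020
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aaggacttgt ctagcagcag gccagggagt gtaagtgtgc tagcccagat gtggtcaccc
       61 agacggctgg ccgagttcga tacccttctt gttccatggg atactagagt ggattaggac
      121 gttagtcttc acttcttgtg gtgcctgtat aaaaggtcga taatttatat cctcattacg
      181 atccgaatca cgtgtcatga atacttgacg ggatcacttc tcctatgccc acacggcaca
      241 acttgatcct catggtggat tcggttccag agttatatag ctaatgagcg ctcagggttt
      301 ccccgcaaca cccaaacaaa ccaaaagatg ccccttagag caacctgagg tggagggagg
      361 tgagcgatga catcctcctg ggtggagcca gtggtggatg aggatgcatt tgagtgtcaa
      421 ccccacgggg tttcgcggcg gttacctgcc cattccgctc tttagaaagc tcccgactgt
      481 gcccaatttt ccacgatgta ccctattcgc gctggaaatg gatgtagaat aattactgag
      541 cgcactgccg gatacggggg gaataaaaaa tccgcaccta gggacccgaa tcctatctta
      601 tgatcacata ggcactgtgg tagtcgctgc ggcgcgtgaa ggacctttgg agaaagtttg
      661 cgaactgcaa ggttgcgcac aagtgggcgg gcacgatggc gccctctgct aggctttatg
      721 cctccccgac ttggtcgccc ggaaagaata tatgtgctaa cgtctcactc gggtctcaca
      781 ccaaagcacc agtggtctag tggtagaata gtaccctgcc acggtacaga cccgggttcg
      841 attcccggct gcgcatgaga cgaaagcgca caggtacgtg aatctttttt gatttggcca
      901 gggctgtagc caatccgcgt aacgtctcag ttttagagct agaaatagca agttaaaata
      961 aggctagtcc gttatcaact tgaaaaagtg gcaccgagtc ggtgcgcaat gagaccggta
     1021 tgagacg
//
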