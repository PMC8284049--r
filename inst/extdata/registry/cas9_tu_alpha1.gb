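LOCUS       cas9_tu_alpha1   1730 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  cas9_tu_alpha1.
ACCESSION   cas9_tu_alpha1
COMMENT     gb_level: L1
COMMENT     gb_backbone: alpha1
COMMENT     gb_marker: kanamycin
COMMENT     gb_provenance: NA
FEATURES             Location/Qualifiers
     misc_feature    1..980
                     /label="alpha1_backbone"
                     /gb_role="backbone"
     misc_feature    61..660
                     /label="KanR"
                     /gb_role="marker"
     misc_feature    988..991
                     /label="OMEGA5"
                     /gb_role="fusion_site"
     misc_feature    992..995
                     /label="VEC5"
                     /gb_role="fusion_site"
     misc_feature    996..1715
                     /label="Cas9_TU"
                     /gb_role="TU"
     misc_feature    1716..1719
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    1720..1723
                     /label="ALPHA_MID"
                     /gb_role="fusion_site"
ORIGIN
        1 aattgcaagc gtgggcgcct cgcggcatgt cacgcacagt taaaaggtga agacggggct
       61 tcccgctaga cgtaacctca ggatagttct agggttggac attcttgatg aactaattag
      121 aaccgtgata cggggagcaa gccactgatc cccagagcgc ttgatggcag gccttagtct
      181 gtggtcagat ggcgccgtag ctgataatgt ctcttattgc gcaccgcgct gtaactccgg
      241 tgcaccaggg aaagaggggt atctgcaatc cgggttcgtc agtagtttat tcgtaggcgg
      301 atagtatata ggtactggaa tgggtcacag caatttgagc gtttgaagga ttatgagtca
      361 gacatccgag ttgaagcgga cgtgtgcgca tcatacttgc gtcactcgag caaaagtggg
      421 agaggggcct agcgtacggc ttgtagtgtc attcagagaa actcgttatc cgcgtaccgg
      481 ccgtcacagt tgttgttttt actgatacta cttgtgttcg taggaagcca ggcctaccgc
      541 gcctgcttcc acggttcggc aaactctcta tttaagacag cacgtcgatc cagataacac
      601 gcacaacaaa ccgagtccta atggcccatg ctagaatcta atccgatctt cacccgacaa
      661 tgaactactc gcccaaatag actggcaggc gtaagagttt cgggcaccgg cgttgaggtg
      721 tgctgccctt tttaacccgg cggtccctat cagatgatag ctaaggcttc cccaccaact
      781 accgggtaag gacaccctta taggcatacc attcccgccc gtactggcta cccctacaag
      841 tactggaggc gccggtatat ccggcactat ccgtgtattc aattctgtgg ggatccttat
      901 cgtgtaaaaa gagccccagc agaatcccga catgcgaaca caatatcggt tgtccgctat
      961 ggcccacgtt tacttcctaa cgtctcacag gggagaatgg gcgatggggc gaaataagag
     1021 gcgattatcc atggtccatc agacgcgtgc ctgcacctct cggctctcga aatggaagag
     1081 cttaggctat tgtaagaacg ccctagacgg gattcgatct aaaatttcat atgagggtcg
     1141 gttgtaacta tgcgtctact tccccggtag gcactcagca gccaactggt agagataaga
     1201 gttcgaagta agacaagatt taggcgggcc agctataaac gtcgcgatca gggacgcctc
     1261 gcatgaacgt aaccgtcacc agcgccagtc caacagaagt cagttagtcc atttggttcg
     1321 acggatgtgt gataacgaga tgtagtaagc ctttctagag tacgagtagc ctggtggaaa
     1381 aagtccggca cccgcggccg aggctggttt tcgggtgcgg aagttgcgca cgtctttttg
     1441 cgttagtttc gcgaatatag aaacctatct ggcacacgtc tttttacctc tgagtctggt
     1501 cttgaaagtg gtgttttgtg aattatcacc tggggcgccg cgcttgctgc aagaaccaag
     1561 gcggctttgt aactgctgta tttccaccct tacatgacgg aggcagctgc cgaggaaggg
     1621 tacactacgg aggtgtgatt tagcgcgctg gtttagggag gcccatacag gcattggaaa
     1681 gctagttttc ttggtgccga ctaatttggg gtcaacgctt acatgagacg
//
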