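LOCUS       omega1           1324 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  omega1.
ACCESSION   omega1
COMMENT     gb_level: NA
COMMENT     gb_backbone: omega1
COMMENT     gb_marker: spectinomycin
COMMENT     gb_provenance: NA
FEATURES             Location/Qualifiers
     misc_feature    1..980
                     /label="omega1_backbone"
                     /gb_role="backbone"
     misc_feature    61..660
                     /label="SpecR"
                     /gb_role="marker"
     misc_feature    988..991
                     /label="VEC5"
                     /gb_role="fusion_site"
     misc_feature    992..995
                     /label="OMEGA5"
                     /gb_role="fusion_site"
     misc_feature    1003..1302
                     /label="lacZ_stuffer"
                     /gb_role="stuffer"
     misc_feature    1310..1313
                     /label="OMEGA3"
                     /gb_role="fusion_site"
     misc_feature    1314..1317
                     /label="OMEGA_MID"
                     /gb_role="fusion_site"
ORIGIN
        1 aacgtaaacg taacaaagag aatgtggcgt aactgagcta ttgcttggct caacaggcgg
       61 aggccccctt tgatctaatt tcgaggcgcg cacaggggga acgttatagt cacttagcac
      121 cgggcgttgg ggatcgagtc gtaagccgag cgttatagtc tgtaggcttc cttgcaacac
      181 acgacttgtc ttattatgaa tcttacttgt gattgagtgc ggcctccgtg gattttgaag
      241 cggtctagag gtaccatgtc cagtggccgt cgattgcccg attctaactc cttttgaacg
      301 atttctacgc gctcctgccc ggcaccgtag gctgagttac attgccgaac aacctatcgc
      361 agcatatacc tagaatttac gggtaatact cgcgtatcaa attaaagtag atgtacccgt
      421 cctgtaatgt atggcagctc gtatttagct tttcttctcg ggataataag gcaccggtaa
      481 aacggcggct ctgacgtgcc gaagactgtt tcgatctttg gcatctgcgc gagaaatttt
      541 cttcatacgg gccaatgacc gtagtgggcc gggcgcatgg ctccaacggc tggccaaccc
      601 cttacggccg accagctagt acacagacgc gaaattgacg cgagctctca cataaaggat
      661 tacatgctcg gcagctgctc tactcctcga ttaagccctt ccaattcatg tgagcgactg
      721 tggatgcgac agctggtctg gagatggcct gcgataaccg tgcccaacgc gatagccgcg
      781 agtttttctg cgtgtctgca tcgcgggggg cagataaaca cgagttttct gtcgtaggag
      841 tggaagtacg gcccagatac aagcgagggc gcagctctgg gaagattcac tgagagttta
      901 ccacggtagg atgcgactgg gactctatct cccttcatgg ttgctgccaa gaggtggttg
      961 cgtcgagcct cccacttcaa ggtctcagga gcaggtgaga cgaaatcatg actcgctaag
     1021 tgtgggtcct gaacacaatt actagaacac tcgctgagta tcttcgggtc actaatttaa
     1081 cgctgaccgt ccctgtatag gtatccggcc ggctcttgtt ccctgtacgt atactcgaga
     1141 tgtgttatcc taatccccgc gaattcattt attctctgta gtgcggttgt aaaggttgta
     1201 ccatatggta cagccaagac tggtaaagtg ctaggtgcct taccatgagt gcgcgcgata
     1261 tgcaataaag acacgtgagt gtgccccgaa caggcgtccg aacgtctcac tcaccattga
     1321 gacc
//
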