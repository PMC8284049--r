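LOCUS       nptii_tu_alpha2  1570 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  nptii_tu_alpha2.
ACCESSION   nptii_tu_alpha2
COMMENT     gb_level: L1
COMMENT     gb_backbone: alpha2
COMMENT     gb_marker: kanamycin
COMMENT     gb_provenance: NA
FEATURES             Location/Qualifiers
     misc_feature    1..980
                     /label="alpha2_backbone"
                     /gb_role="backbone"
     misc_feature    61..660
                     /label="KanR"
                     /gb_role="marker"
     misc_feature    988..991
                     /label="ALPHA_MID"
                     /gb_role="fusion_site"
     misc_feature    992..995
                     /label="VEC5"
                     /gb_role="fusion_site"
     misc_feature    996..1555
                     /label="nptII_TU"
                     /gb_role="TU"
     misc_feature    1556..1559
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    1560..1563
                     /label="OMEGA3"
                     /gb_role="fusion_site"
ORIGIN
        1 aagaagatgt tataactatc aagttggcag caatacctgc cggtagcccg ggatgactgc
       61 gccggacgtg cctgcttatt ggaatccaat aggactcaag cgccagtagg gtacagcact
      121 tgatcaagcc cctggtttgg tgcgaccata ccctaaacag gaggatcacg atcagaggcg
      181 cgacccaggg agtcatactc gcgtgctgga catgctgtca gtcgcccact caataaaaag
      241 aattcgaggg gcgagatgcc gacttccggg cagccggagg gatgacagcg tttggtcccc
      301 cgacagtata ggttaaaatg gatttcccca ttctgtcgtg atagatactg aaactgcata
      361 ccgaggcgta gaagtatcct tgggacaacc atcagtcacc agtggccgag tatcatgcac
      421 gaagagacat ggaattttta aagccgacat gcgtatccgg cccgataagc gctctcgcat
      481 tgaggatcgt tccctggacc caatggagct agacttcttc gactgccagc cgagactaaa
      541 cgcgatcgta cggtgtgatt ctcaacaaat tgtacctagc agtagccctc tagaagtgcc
      601 caggcgagcc gaaatgcgca ctctaattgg aggttcatta tcggatgtct tactagaacc
      661 ggtcttccag tacaagtgta cactatcagt ccgatgtcgc cacgagctag cggcgctggc
      721 tgggttatac tgattacgta tacaacccat acttggccga ggggtagatt gaacaccagt
      781 aacccggcgc tcgccctact ccaggacggg cctaacaaca ctggaggcca gtgccttcat
      841 ggtataagca atggaagcgt ccggaaacgc cgggagaacc gttttgggac acgatgtagg
      901 gccccgagcc cacatctgaa actcaactat caccctcgtt ccattggcta ctatactaaa
      961 catggaccta cgctcccgaa cgtctcatac aggagaatct ccaatgagtc tattggtcca
     1021 atattagcca ctactagaag gcgatatgga cccaagaaag gatattattg gtaagcaaga
     1081 gaggacgtga cggtatcata caccagtatt acgctataac taaagccccg tactgacaat
     1141 acggaccgca ggatcttgcc atgccattcc caggtcgaaa aggtaagttc aacttacctt
     1201 ttaactcgag gtccatagga taataggaag cggagccctt ccgcgatgca cttgattctc
     1261 agcgcacgac cgacgattta gcctcatgaa tggttcgctc atgagaagta tttccgtaac
     1321 gtacactctt cgttgtcgtg ctcgtacgca caccgcagcg ctcccgtaca tcctacgaag
     1381 gtgcaccacg ctcagtaaca aaatgatcgg gggcctaagg agtcctggcc ttatcaggcg
     1441 tagccattgg agacttaaat ccggcgtagt agcaacgccc tatcaccaac cggctacagg
     1501 ctgagggagg atggaattgt accttgggtt ccccagaaga ctgtcaacga attaacgctc
     1561 tcatgagacg
//
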