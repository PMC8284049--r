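LOCUS       nptii_tu_omega1  1570 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  nptii_tu_omega1.
ACCESSION   nptii_tu_omega1
COMMENT     gb_level: L1
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
     misc_feature    996..1555
                     /label="nptII_TU"
                     /gb_role="TU"
     misc_feature    1556..1559
                     /label="OMEGA3"
                     /gb_role="fusion_site"
     misc_feature    1560..1563
                     /label="OMEGA_MID"
                     /gb_role="fusion_site"
ORIGIN
        1 aaccaacttc tcgtgcgtcc gccgtttcta tcacgcagtc cgcgaacgac aaggtgggta
       61 agacactccg tttaccgtag ttgacctcgc tggcacacgc acaatgtcat tggacccagt
      121 catggccctc agaacgcata tcctaaatgt tgtctcccgt ttgaggaaag gctggcttga
      181 agctttgcgt tcttctattt aaatgctagg gccaatcacc ctaatacact cgcccatggc
      241 ataccaggat cagctacgcc tgatagcccg ggaccaccgt caaacataca gcatcatggc
      301 gggcccctct attcacattc gatccattaa cgactgcaag ccgctaagct taagaaactg
      361 tggcaactac gcaattcgca ttcactataa acaaatactg gtgtagagtt ccttacccat
      421 gtatgaaacg cttaaactat ccgcaccgct tccgatcgag atctctccga tgttccgagg
      481 ttgatagctg gctatgaaac cgtcacatgt agttcttttc cttaaagaaa gcattaatca
      541 tggggtcata ataattttta aagagatggt atcattagtt tttccgcgcg atatgacgaa
      601 ggatgaattc aaggcatggg gcgcgtgagt aacgtgggct caggatgttg gtcacttaac
      661 acttgatata acttgtaacg tccctttggg tgaatatgga tcgcttggcg cttgacgcac
      721 cgtgacgatg ttagcccagc catcttggag catacgacgc atttagtcaa caggccaatg
      781 tactaaaaat cgcattggcc ggtataatgt gcttccctat cttgcccctg actcgttgat
      841 gagttttgcc cctttaccga cgtcataaca tatccctaga gcataggcca tgcgtgagtc
      901 agtcttgacg aagcgcgtat ccgaagggta atggaagtca agtagatgtt ctgaaattta
      961 tagttcacca gcggcagaaa ggtctcagga gcaggaatct ccaatgagtc tattggtcca
     1021 atattagcca ctactagaag gcgatatgga cccaagaaag gatattattg gtaagcaaga
     1081 gaggacgtga cggtatcata caccagtatt acgctataac taaagccccg tactgacaat
     1141 acggaccgca ggatcttgcc atgccattcc caggtcgaaa aggtaagttc aacttacctt
     1201 ttaactcgag gtccatagga taataggaag cggagccctt ccgcgatgca cttgattctc
     1261 agcgcacgac cgacgattta gcctcatgaa tggttcgctc atgagaagta tttccgtaac
     1321 gtacactctt cgttgtcgtg ctcgtacgca caccgcagcg ctcccgtaca tcctacgaag
     1381 gtgcaccacg ctcagtaaca aaatgatcgg gggcctaagg agtcctggcc ttatcaggcg
     1441 tagccattgg agacttaaat ccggcgtagt agcaacgccc tatcaccaac cggctacagg
     1501 ctgagggagg atggaattgt accttgggtt ccccagaaga ctgtcaacga attaactcac
     1561 cattgagacc
//
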