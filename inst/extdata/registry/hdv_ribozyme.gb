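LOCUS       hdv_ribozyme     921 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  hdv_ribozyme.
ACCESSION   hdv_ribozyme
COMMENT     gb_level: L0
COMMENT     gb_backbone: pUPD2
COMMENT     gb_marker: chloramphenicol
COMMENT     gb_provenance: NA
FEATURES             Location/Qualifiers
     misc_feature    1..820
                     /label="pUPD2_backbone"
                     /gb_role="backbone"
     misc_feature    61..660
                     /label="CmR"
                     /gb_role="marker"
     misc_feature    821..824
                     /label="UPD5"
                     /gb_role="fusion_site"
     misc_feature    832..899
                     /label="HDV_ribozyme"
                     /gb_role="HDV"
     misc_feature    832..835
                     /label="SPACER_HDV"
                     /gb_role="fusion_site"
     misc_feature    900..906
                     /label="PolIII_terminator"
                     /gb_role="terminator"
     misc_feature    907..910
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    918..921
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aattgcatga tccgggcagc tgggacagga cggctaatta tcaatccggt tcaaaattct
       61 agtacactca aacaacatct ttcaatttta acgaggtgca cgtccatact gtccgttgga
      121 tcaaggagcg aacttgtgcc ccgctcttga tcgttagagt ctccatttcg accttaatag
      181 aatcgacgct gcgctgatga catgctcaca ttggacctca tctgggcagc atcgatgcta
      241 ccaaaccaac tatcatttcc gatttctcag cgtagtgtat gaaggtttac cttacaattt
      301 ccgtcccgtt agatggaact cagaggtgta cacggcttat tatacgtagt caacttggcg
      361 caggtcggga atatcatggg gcgccctatg tacaggcgtt gcacatgggt cgtgggcctt
      421 gtgagagagg gcgaatatta tgcgcacacg aaccgacaag agtgtggcag cttgttgatg
      481 gcgtcctaca cattcgagtc cctggcgtaa gctctcgact tacgataagt acaatcagca
      541 accacagcga cgttcgtgga tgataatata tgcaacgggc gaatctggcc caactctggt
      601 attgaactaa ggattcatct tcacttcttg tacctctcgc tcgaaacggt tgccaaactc
      661 ggcattctgc tatgtcaacc cccttcaaca agttcaccgc cctacgaagg accagatgat
      721 ttagtaacgg aatttttgtt gggcgggaag gtgatagcgc acagacgata attttaatct
      781 ggcgtaaccc tctgatgaac tagatcgact attccggcaa ctcgggtctc agtccggcat
      841 ggtcccagcc tcctcgctgg cgccggctgg gcaacatgct tcggcatggc gaatgggact
      901 ttttttcgct tgagaccggt a
//
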