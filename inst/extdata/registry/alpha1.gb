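LOCUS       alpha1           1324 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  alpha1.
ACCESSION   alpha1
COMMENT     gb_level: NA
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
     misc_feature    1003..1302
                     /label="lacZ_stuffer"
                     /gb_role="stuffer"
     misc_feature    1310..1313
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    1314..1317
                     /label="ALPHA_MID"
                     /gb_role="fusion_site"
ORIGIN
        1 aaggtgtgcg ggaccaaaac caatggagcg aaaccacttg ataccaagcc atgcaggtgg
       61 gcaaccttga cctctcaacc acaacagttt aatgtggcgg gggccgactg gcggtatatt
      121 aacgccatgt atggagttgc tgaaccaccc cgcgtagagc gtacctccgg ttggttctcg
      181 ttcttattta gaaatgtgct tctggatgcc cttcgagaaa tacgtaacct aatcatacat
      241 caaattatcg ataacgccag acctgtagtg cactatctga ctacatgagg ttgcaggtag
      301 attattggca ttaataatac cccgctattc tccgcttaag gacagctacc ggcataatcc
      361 tttaggcgtt cctcaagtag cgcatttcac gatgcccagg tttcgcacga gcgtactact
      421 ataagaatga atccacgact agttgtcctc ctcagttagt gaggaaccta gagagtcctt
      481 ataggcactg gaatgcccct tttggctctc cgccgaggag ggaacttggt tctcttcaga
      541 tgctcaccta caggtcgtgg tcagcacgtt cgcttgatgc gcgtatgctc cgacgacggg
      601 ctaagctgtc tctcaatgtg ccgggagata tattgactca cggaagtcca cccggcattg
      661 cactaatagg aacgctcgcc agattgttga taactgtccg tgaggccggt ctacaaccgc
      721 ggactcgact gatcagagtg accttcatta attagcagaa cgcatttgtc ttatgactgg
      781 ctacatatgc ccggtcgcta cctgggtgtc gcgaggatac tcgcaccaga cagctttctg
      841 gacatggcca aaagagctag ccaagaagga aggtttctcg ttcacagtga gcatgcttat
      901 tggcacagtc gggtggcgtc ttctcagttg cggccgcgca cgctgatttg tccagcaagg
      961 tctacgcgct atagaactaa cgtctcacag gggagtgaga ccaaacgtgt acaaggaggc
     1021 aacaaaaacg gaggcgtata tgccaatccc gtaggccggg acagggacag ctcgtttgcg
     1081 gactatttgc atgatccctg aggttgaaat aaggtaattt cgaccagttg tgtcgcgcta
     1141 tagcttcgcg gcggtcttgc tcttatgtgg cgtgtgcctt ttcgtttgtt tcagcttttt
     1201 cgcccaatgg tcggcgcacc ttagtcgata ccggcatatg gcgtgaaatt ttatgagagc
     1261 ctttttacct cctaatcggc acttcagtga tacaacgtaa aaggtctcac gcttacatga
     1321 gacg
//
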