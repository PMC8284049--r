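LOCUS       alpha2           1324 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  alpha2.
ACCESSION   alpha2
COMMENT     gb_level: NA
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
     misc_feature    1003..1302
                     /label="lacZ_stuffer"
                     /gb_role="stuffer"
     misc_feature    1310..1313
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    1314..1317
                     /label="OMEGA3"
                     /gb_role="fusion_site"
ORIGIN
        1 aagatcatat gtgaagagac taagggagcc atttatgttc gctaggcaat gcgagagtgc
       61 gtgttgcgcc tagctcggaa cgcttcttat cctcattccc ccgtgattgg gtattactcg
      121 ctcatcccta acgaaggttc aagacaactg gtccggatgg actgaagggg ttttggcgga
      181 taacactgca attttcccta tgacagtggt ttcacttgag cactcttaaa gtacgccata
      241 tctactgggc tactcattcg gtcgacttgt tacgtaatgg tagagaacag gctgaacatt
      301 catactgctt tacctcctct tttcgcacga tactcaggtt tcagctagta tgagtttcga
      361 ctgtcctacc cggtgtaaag ctaccatagt catccattct ccgtgtcggg gcacaccagc
      421 tcagccgatg tacgtgccta tagatggagg caagtagtat gcatacaccc ctccgactcc
      481 actgaaggtc gtcgagctgg gccttctact cttgctcgtg ctaattccct ttatcaacat
      541 ccgaacacga caccgcggtc agttgcgatc ttgtaacata ggactaggaa gttcggcaag
      601 ggcccactcg ttcgcatatc catgagtatt accgaccgcc cagggataaa aatcgcgact
      661 tcgtcattta atctgtacta gcaaattgcg tataattccc cttgatcggc ccaagcaggg
      721 aatttgacat catctgaacg agtgacttga tggcagcgct caagggcatt ggatctcgga
      781 ggatcaggag attccatatc gtagagccta acctctagga cacacttcga taagtgcgcg
      841 gaggctgggt ggtcggttcg aacttatctg ttaggcaccc tctggatcta acgcgttccg
      901 cgggattcca ggaattcaaa tggcattagt gctagggtgg atcactcggt cgaaacagta
      961 ccaacgcaga ctgagcccaa cgtctcatac aggagtgaga ccaagtactt ccgcgggagc
     1021 cgtttatact ctaatcgaca ttgggtagtt gtcaactaga gtcgcaagcc catccacctc
     1081 tcgcgtcggt gtaacagtcc gatgtgacat tacagtatgc catttttcga ggcgttgttg
     1141 acttcggaac tccctgacat ttcgggatct tattaccagg cgaggcggca cgcgaatgcc
     1201 caatatgact gaacgcgacg ataccggacg ttcacacgat aatacgtaaa taacacaatc
     1261 actgcaattt cacaggaaga gctaccccta atgcagaatc aaggtctcac gctctcatga
     1321 gacg
//
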