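LOCUS       pol3_promoter_mu 1030 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  pol3_promoter_multi.
ACCESSION   pol3_promoter_multi
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
     misc_feature    832..835
                     /label="VEC5"
                     /gb_role="fusion_site"
     misc_feature    832..1015
                     /label="U6_PolIII_promoter"
                     /gb_role="promoter"
     misc_feature    1016..1019
                     /label="POS0"
                     /gb_role="fusion_site"
     misc_feature    1027..1030
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aagaccccca attctaccaa gatcaagcta cggagtggtc acgtactgct ggacatacgc
       61 ctcagatccc ccatgcgtgt agcgggtctg gccaagatgt aatttaaggt cgaatgcaac
      121 cagcccgtgt gtgaagcaga attcaaattt gaggcggtat ttagattgtt gaacaacttg
      181 ggagcggggc tccgtatcct acatactagc ctgcagtagg acacaggaag ctgaaaactg
      241 tgtgcatgag ttcctccgtc cggggtgctt cggatctcgc atagtcacag cgcaaactcg
      301 gggtgctcgc attatgttag attgcggggc tccagccagt agtgtcgtgt acagtatagt
      361 taagcgatct aaaaagcgct atctggaaac atcaaatagt gccactggat cgacattgga
      421 ttgccggtct gacttgacgc gtgaataaac ggctcagata gcgcacgact cacgtcacgt
      481 atccctttag gctttttatt gtagtacttt tagggcatgt tataacacta gtacctgagt
      541 tatagctcga aaaaaactat gggtcgagag agttacgatt cagcgtcggg ccggacggtg
      601 cactatggac catgacagcg ccatgaggcc ccccacttga atagaataaa cgccatctta
      661 ggatttgact ggttataggg gcactcttcg aaattcacac agaggagccg caccgatcgg
      721 ttctgaccat aaagtcgagt actgcttgca gaaaactatc actgcaccgt gcgaggtatt
      781 cgtaaactgc gttaacccgt cacgcgtccc taggagataa ctcgggtctc aggagaacta
      841 gaggcatccg cgtcctccgt cggcttgggt ttcacccgat gtcctgaact gggaaagtgg
      901 gtgcctctac cccacgcggg atcgcaaacg tgaaatattg gcggggcgac cagcacctca
      961 agggcagtgc tcaaataagt tgaccagcca atctcgaaaa cgtttctgtt ggtaacacct
     1021 gagaccggta
//
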