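LOCUS       cas12a_upstream  1047 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  cas12a_upstream.
ACCESSION   cas12a_upstream
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
     misc_feature    1016..1036
                     /label="crRNA_DR"
                     /gb_role="DR"
     misc_feature    1033..1036
                     /label="DR_SPACER"
                     /gb_role="fusion_site"
     misc_feature    1044..1047
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aatgttttac gaagctggga aacacctatc cacccgtttt gcgcatggcg tgttctaggg
       61 agagtgaact tctacggaaa gctgaatgat atactcgaca ctgggctcgc tttagagtga
      121 cactaggacc ggctataggc acgactctcg attcatgtta cgggtgcaga cgtgcttatt
      181 tcaattacta cttgctacct atcgagccag gggatatcga actaatgcat tgagcccccc
      241 agttcggctt ggatggcgag ctacgacccg cgcgtgaacc ggccgaccat agttgaaagc
      301 gcagccgctc ggaggctcgt gattcgggtt ctctaaatcg cgtttttccc gagctatctc
      361 agccccagaa tacactacag tactacgcgc cgttcatcgt aatggcctaa attgcgcaag
      421 gagtcgggca agagtattca gttaaattta tccgagatat gcacatagta ttcgtgtggc
      481 ttcatacccg tctgagctcc ttcaggcatc tgttcatact gtccgcgctt tataacacac
      541 ggaacatgta cttgtcgtta cggagagtca gccagcgatt agcgttccac catagagaac
      601 actcatctga ccgtgctagc ttggactcat cagccattta agcgccttac catgttactg
      661 ggatatcaat attgttatgc cgcatcccct tgcagttgca ataaagcaca tattcttggg
      721 cacccactgg ggggagagag cccctagtat gtgctgtgat tcgcattatg tgcacggtgc
      781 cttcgcgtgg aagccctgtg gcttagggag ctcgtctgaa ctcgggtctc aggagaacta
      841 gaggcatccg cgtcctccgt cggcttgggt ttcacccgat gtcctgaact gggaaagtgg
      901 gtgcctctac cccacgcggg atcgcaaacg tgaaatattg gcggggcgac cagcacctca
      961 agggcagtgc tcaaataagt tgaccagcca atctcgaaaa cgtttctgtt ggtaataatt
     1021 tctactaagt gtagattgag accggta
//
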