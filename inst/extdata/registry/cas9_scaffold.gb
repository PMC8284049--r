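LOCUS       cas9_scaffold    929 bp    DNA     circular UNA       01-JAN-2026
DEFINITION  cas9_scaffold.
ACCESSION   cas9_scaffold
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
     misc_feature    832..907
                     /label="sgRNA_scaffold"
                     /gb_role="scaffold"
     misc_feature    832..835
                     /label="GUIDE_SCAFFOLD"
                     /gb_role="fusion_site"
     misc_feature    908..914
                     /label="PolIII_terminator"
                     /gb_role="terminator"
     misc_feature    915..918
                     /label="VEC3"
                     /gb_role="fusion_site"
     misc_feature    926..929
                     /label="UPD3"
                     /gb_role="fusion_site"
ORIGIN
        1 aagtagtgtc caaaagcttt gcaaaatatt ccatcaaagt ttgaccatcg gcagactgtc
       61 tacagtgaac atcggcggat acccccagtt gtcaaaccaa attgcgttgg ttgctactgt
      121 atgagtacag agtcatcaac ggagccgggt gcagcagtat gtggcaaacc cgttttgtga
      181 ttactaagtt ggtagacggc caactctgga gccggtcggg cttcgttcgc ggacgtcatc
      241 accgtttccg cacatcttga ggagcgttat gcacggcgtt gaataaaatg tgttgagagc
      301 tctgacatac aggtttaata aagccgccct accccctcac acgagccgca acgacgaagt
      361 gtcatcataa tggagccatc tgttacacca actgttgacc gatgcgttag ttggtataag
      421 cctacctgct ggacacaaaa tgtactgtga caagatcact gtcctagacg gatttcctcc
      481 cgccgttgcc gaggatcgat ccctaaactt acaagctaag ttacaccgtt gtagtgaata
      541 cataaccgac tggagctgcc taggcattat taatttctaa ccgttgatgt gaaggttgca
      601 ttattggaga cactgacgtg atttcccgac gccaagtcgt tgccaggagt ctacaacgaa
      661 tatacttact cgtgcggcgg cttctgtcca cagcttgtat gccatgggcc aagcgatgcg
      721 cgttagtccg cctcgtgtct ccgtggcacg agtgtagctc cccattgagt ctggatacga
      781 gacaggacat gttccgacta cgccagagca atctttgcaa ctcgggtctc agttttagag
      841 ctagaaatag caagttaaaa taaggctagt ccgttatcaa cttgaaaaag tggcaccgag
      901 tcggtgcttt ttttcgcttg agaccggta
//
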