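Package: braidr
Title: Type IIS Cloning Simulation and CRISPR Multiplex Construct Design
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline implementation of the GoldenBraid (GB) modular
    cloning standard for plant genome engineering: a Type IIS
    restriction-ligation grammar (BsaI/BsmBI, 4-nt fusion sites, the
    alpha/omega double loop of destination vectors), an in-silico
    digestion-ligation engine that predicts assembly products with
    diagnostics, and the complete set of single and multiplex guide-RNA
    design tools for Cas9 (tRNA-spaced polycistronic arrays, up to six
    guides, including MS2-aptamer scaffolds) and Cas12a (direct-repeat
    arrays with HDV ribozyme trimming, designed as synthesis-ready
    fragments). Constructs are emitted as annotated GenBank files with
    oligo order sheets and laboratory protocols, and an in-planta
    RNA-processing simulator (tRNA excision, Cas12a self-processing, HDV
    cleavage) verifies that every designed array matures into exactly the
    planned guides. Editing-efficiency estimates can be binned into
    genotype categories (negative, chimeric, heterozygous, biallelic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
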