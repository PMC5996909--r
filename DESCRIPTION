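Package: repeatlens
Title: Motif-Level Analysis of the EIF4A3 5'UTR Tandem Repeat Locus
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the complex tandem-repeat locus in the
    EIF4A3 5' untranslated region, whose expansion causes Richieri-Costa-Pereira
    syndrome. Implements exact motif tiling of repeat alleles over the CA-18nt /
    CACA-20nt / CGCA-20nt motif alphabet, allele and diploid genotype
    classification, CpG accounting, IUPAC-level deconvolution of heterozygous
    mixed Sanger amplicons, an unequal crossing-over simulator with derivation
    search for allele origins, pairwise linkage disequilibrium (D, D') and
    EM haplotype phasing over flanking SNP panels, dual-luciferase reporter
    normalization with per-motif expression-effect estimation, bisulfite clone
    methylation quantification with conversion and identity filters, and a
    synthetic-cohort generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
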