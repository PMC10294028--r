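Package: sweepscan
Title: Selective-Sweep Scans from Pooled Heterozygosity and Windowed Fst
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate selective-sweep regions between two populations
    from biallelic SNP genotypes. Computes windowed pooled heterozygosity (Hp),
    mean per-site fixation index (Fst), and nucleotide diversity (pi) in sliding
    windows, Z-transforms the genome-wide window distributions, calls extreme-tail
    outlier windows, merges them into regions, and intersects the Hp and Fst
    evidence tracks. Downstream, maps regions to gene annotations, filters genes
    by missense consequences, and tests gene-set over-representation with a
    hypergeometric test and Benjamini-Hochberg correction. Includes a seeded
    two-population genotype simulator (Balding-Nichols background with planted
    near-fixed sweeps) so the whole pipeline is testable without external data,
    plus readers and writers for VCF, BED, GFF3 and TSV interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
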