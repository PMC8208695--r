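Package: spirorate
Title: Substitution Rates and Genome Degradation in Bacterial Endosymbionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tip-dated substitution-rate estimation and comparative
    genome-degradation analyses for serially sampled bacterial endosymbiont
    genomes. Builds per-library coverage masks, restricts variant calls and
    coding sequences to positions covered in every sequencing library, counts
    substitutions at third codon positions, and converts them into per-site
    per-year rates. Classifies variant effects under the Mollicutes genetic
    code (translation table 4, TGA = Trp), summarises strand-collapsed
    substitution spectra, flags truncated (likely pseudogenized) orthologues,
    computes coding densities, applies a similarity rule for prophage-related
    genes, and derives syntenic blocks with per-kilobase CDS-density
    differentials from pairwise alignment hits. A synthetic genome-evolution
    generator with full ground truth makes every stage testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    data.table,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
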