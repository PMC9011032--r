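Package: selfsynt
Title: Recombination Maps, Chromosome Domains, and Synteny in Selfing Nematode Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative genomics of selfing Caenorhabditis species:
    construction of genetic maps from selfed recombinant inbred line (RIL) panels with
    marker quality filters (segregation distortion, linkage-group membership, local
    allele-frequency deviation, locally excessive recombination), hidden Markov model
    genotype imputation from low-coverage read counts, Marey-map domain calling by
    two-breakpoint segmented linear regression, an ortholog-rank collinearity statistic
    for contrasting genome rearrangement between selfing and outcrossing species,
    genome-wide divergence summaries (amino-acid identity of single-copy orthologs,
    SNV density, inversion-size filtering), and assembly/annotation QC arithmetic
    (N-split contig metrics, QV conversion, repeat copy-number estimation, telomere
    scanning, reciprocal-best-hit protein-length concordance). Includes simulators for
    RIL genotype panels under piecewise recombination landscapes, rearranged gene
    orders, and low-coverage marker observations, all with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
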