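Package: keyvar
Title: Key-Ancestor Re-Sequencing Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational stages of a key-ancestor re-sequencing study in a
    livestock population: construction of the pedigree-based numerator
    relationship matrix and iterative selection of key animals capturing
    maximal genetic diversity; sequence-versus-array genotype concordance
    (non-reference sensitivity and discrepancy) under a phred-quality filter;
    variant classification and catalogue summaries (per-chromosome counts,
    Ti/Tv, novelty); strand-aware functional annotation of variants against
    single-transcript gene models (promoter, UTRs, CDS, splice sites, introns;
    coding effects via codon translation); pseudoautosomal-boundary detection
    from male X-chromosome heterozygosity via a binomial changepoint; and
    recessive-disorder mapping by Fisher allelic association and shared
    homozygosity segments. A synthetic-data module generates all inputs with
    known truth (pedigrees, gene-dropped genotypes, an annotated toy genome
    with planted variants, paired array/sequence calls with coverage-dependent
    error, and male X genotypes with a planted pseudoautosomal boundary).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
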