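Package: opsinquant
Title: Paralog-Specific Opsin Expression Quantification and Cone-Ratio Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing the near-identical OPN1LW (L-opsin) and
    OPN1MW (M-opsin) transcripts and for downstream cone-ratio genetics.
    Discovers diagnostic nucleotide sites between paralogous transcripts,
    designs discriminating in situ hybridization probe windows, quantifies
    paralog-specific expression from aligned short reads by diagnostic-site
    pileup counting with a normalized pileup statistic and a pooled mixture
    estimate, converts flicker-photometric electroretinogram (FP-ERG) signal
    fractions to corrected percent-L cone ratios, and runs a targeted
    association scan (Freebayes-dialect variant QC, minor-allele-frequency and
    call-rate filters, windowed LD pruning, standardized-genotype kinship,
    eigenvector covariates, per-variant linear scan, Bonferroni correction).
    A synthetic-data module generates paralog pairs, mixed-origin reads,
    structured haploid genotypes and phenotypes with full ground truth so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
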