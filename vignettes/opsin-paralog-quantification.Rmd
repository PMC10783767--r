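---
title: "Distinguishing near-identical opsin paralogs: methods and design"
author: "opsinquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing near-identical opsin paralogs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsinquant)
```

## The problem

Human long-wavelength (L, *OPN1LW*) and middle-wavelength (M, *OPN1MW*)
cone opsins are encoded by adjacent X-linked paralogs whose protein
sequences are roughly 96% identical and whose mRNAs are roughly 98%
identical. Probes, antibodies and short sequencing reads therefore cannot
distinguish the two transcripts by overall similarity; everything must be
driven by the small set of nucleotide positions at which they differ.
opsinquant treats those **diagnostic sites** as the primitive object and
builds four analyses on top of them:

1. discovery of diagnostic sites from a pairwise transcript alignment, with
   transcript/exon/genome coordinate mapping;
2. design of discriminating in situ probe windows;
3. paralog-specific expression quantification from aligned reads by
   diagnostic-site pileup counting;
4. cone-ratio phenotype handling (FP-ERG correction) and a
   targeted-sequencing association scan against the %L cone ratio.

A synthetic-data module generates paralog pairs, mixed-origin reads and
structured haploid cohorts with full ground truth, so every stage is
testable end to end without external data.

## Diagnostic sites and coordinates

`align_paralogs()` is a global Needleman–Wunsch alignment (via Biostrings)
with affine gaps. The default scoring — match +1, mismatch −1, gap open −5,
gap extend −1 — is deliberately unremarkable: for paralogs above ~95%
identity the optimal alignment is insensitive to the scheme, and all
parameters are arguments for users who care. `percent_identity()` divides
matching columns by columns where both tracks are non-gap, the convention
under which near-identical paralogs are usually quoted; a gap-inclusive
denominator is available as an option.

A diagnostic site is an alignment column where both transcripts carry a
definite, differing base. Ambiguity codes (N) never form sites, because no
probe or pileup can discriminate on them. Coordinates are 1-based and
fully closed throughout, matching how probe intervals and transcript
positions are conventionally printed.

The bundled table `opsin_sites()` records the 20 positions distinguishing
the two opsin mRNAs, with exon labels and GRCh38 chrX coordinates.
`fit_exon_map()` estimates one transcript-to-genome offset per exon from
such a table and **flags** rows whose own offset disagrees with the exon
majority rather than silently correcting them. The bundled L-opsin
annotation triggers this flag: its exon-5 genomic offsets jump by 8 between
transcript positions 895 and 901, while the M-opsin offsets are constant in
every exon (and round-trip all 20 positions exactly). A related feature of
the same region is that the L-to-M transcript-position offset changes from
−22 to −30 inside exon 5, i.e. an 8-nt length difference between the
transcripts; the probe module therefore maps intervals between the two
transcript frames using the offset of the nearest diagnostic site
(piecewise constant between indels) instead of one global constant.

## Probe design

`enumerate_discriminating_windows()` scores every fixed-length window by
the number of diagnostic sites it contains. `select_probe_pair()` chooses
one window per paralog under a lexicographic objective:

1. maximize the number of distinct diagnostic sites contained in **both**
   windows;
2. break ties by the size of the union of covered sites;
3. anchor each window so it starts at the first diagnostic site it covers
   (leftmost among remaining ties).

The primary criterion is the number of *shared* sites, not the union,
because each probe must discriminate on its own: a BaseScope-style probe
hybridizing a region with no differential nucleotides binds both paralogs
regardless of what its partner covers. An overlap constraint (≥ 1 shared
aligned column, on by default) encodes that the two probes target the same
region. Under this objective the bundled opsin table with lengths (42, 40)
yields exactly the published pair — L-opsin 880–921 and M-opsin 902–941,
each containing 8 differential nucleotides — and the suite verifies by
exhaustive search that the selection attains the optimum on small random
instances. No thermodynamic scoring is applied; GC content is reported for
information only.

## Diagnostic-site pileup quantification

`pileup_at_sites()` counts read bases over each site (one base per read per
site; deletions contribute nothing; CIGAR insertions/deletions/clips are
honored). Bases below the phred floor (`min_base_quality = 13`, ~5% error)
are excluded from both counts and depth. Duplicates are not removed at
this stage. `assign_site_counts()` partitions each site's depth into
`count_a`, `count_b` and `count_other`, and `normalize_counts()` computes
the per-site expression statistic: allele count divided by the sample's
total read count, scaled per million by default (the scale, and whether
"total" means aligned or sequenced reads, are the caller's choice).

`estimate_mixture()` pools counts across sites,
`fraction_a = Σ count_a / Σ (count_a + count_b)`, with a 95% Wilson score
interval on the pooled informative count. The interval treats pooled
allele observations as independent, which is correct when diagnostic sites
are farther apart than the read length (each read then contributes at most
one informative base). The real opsin table violates this — several of its
sites sit within a few bases of one another — so on such data the interval
is anticonservative; the calibration simulations therefore place sites with
a minimum spacing above the read length (`make_paralog_pair(min_spacing=)`),
and users pooling clustered sites should read the interval as a lower bound
on uncertainty. With a per-base error rate ε, a fraction ≈ 2ε/3 of
diagnostic-site bases land on the two non-allele bases (`count_other`), and
cross-allele errors bias the pooled fraction by O(ε), both of which the
suite checks.

## FP-ERG cone-ratio correction

The flicker-photometric ERG pools cone signals, with each M cone
contributing w = 1.5 times the signal of an L cone. Writing the summed
signals S_L = n_L and S_M = w·n_M, the observed L signal fraction is
s = n_L / (n_L + w·n_M); solving the two-cone linear model for the count
fraction gives the closed form

$$\%L = 100\,\frac{w s}{1 + (w-1)s},$$

which is strictly increasing, fixes 0 and 100, reduces to 100·s at w = 1,
and dominates 100·s for w > 1. The inverse map is exact
(`signal_fraction_from_percent_L()`), and w is a parameter. Raw %L values
above 100 — a known saturation artifact of the ERG normalization near pure-L
retinas — are clamped to 100 with a warning on import; the exact nonlinear
normalization that produces them is upstream of this package and is not
modeled. Decile summaries (`genotype_by_decile()`) use ten equal-width
bins on [0, 100], matching the conventional decile axis, not equal-count
quantiles (configurable).

## Association scan

The cascade mirrors a standard targeted-sequencing workflow, implemented
natively:

* **Record QC** (`filter_variant_calls()`): QUAL > 10 × AO, at least one
  alt read on each strand (SAF, SAR ≥ 1), alt reads placed on both sides
  (RPL, RPR ≥ 1), at least two alt observations, then duplicate records
  removed keeping the first. The phrase "quality greater than 10 times the
  number of additional observations" admits more than one reading; the
  conventional quality-per-alt-observation rule (QUAL > 10·AO) is the
  default and `qual_rule = "qual_gt_10_dp_ro"` gives the DP−RO variant.
  Likewise "at least 2 reads … balanced up- and downstream" is read as
  RPL ≥ 1 ∧ RPR ≥ 1 ∧ AO ≥ 2, with `place_min = 2` available for the
  stricter reading.
* **Variant QC**: MAF ≥ 0.035 on non-missing alleles (respecting ploidy)
  and call rate ≥ 0.90.
* **LD pruning**: greedy left-to-right, dropping a variant whose squared
  Pearson dosage correlation with an already-kept variant within 100 kb
  reaches 0.75. The left-most variant of a correlated set is retained (the
  retention rule is not standardized across tools; this one is simple,
  deterministic and audited by an all-pairs post-condition test).
* **Kinship**: K = XXᵀ/m on mean-imputed dosages standardized by
  ploidy·p and √(ploidy·p(1−p)) — uniform weights, frequency power −1.
  Monomorphic variants are excluded with a warning.
* **Covariates and scan**: the top 5 eigenvectors of K (orthonormal, sign
  fixed by the largest-magnitude entry) enter a fixed-effects linear model
  `%L ~ intercept + dosage + eigenvectors`, fitted per variant. The
  covariates are projected out once by QR, making the scan a single pass of
  simple regressions that is algebraically identical to per-variant `lm()`
  (asserted to 1e-10 in the tests). Kinship is retained and returned; a
  full mixed model is not fitted, since the eigenvector adjustment is what
  determines the reported p-values here.
* **Multiple testing**: Bonferroni at α/m over the variants actually
  tested. At m = 2890 tests and α = 0.05 the threshold is 1.73 × 10⁻⁵.

Male-X (hemizygous) dosages are coded 0/1, not 0/2, so β is the effect per
alt allele on the 0/1 scale — this doubles β's magnitude relative to a 0/2
coding and is the scale on which the package's effect sizes are quoted.
Missing dosages are mean-imputed for both kinship and the scan. Variants
left with no residual variance after covariate projection are skipped with
a recorded reason. A phenotype lying exactly in the covariate span is
detected and returns null effects (β = 0, p = 1) rather than noise-driven
statistics.

## Synthetic data

* `make_paralog_pair()` plants exactly `n_diffs` substitutions (optionally
  with a minimum spacing) in a random background; the planted table is the
  ground truth for the site finder.
* `simulate_reads()` draws each read from paralog a with probability π_a,
  uniform starts, substitution-only errors at rate ε, uniform Q40
  qualities, and emits true alignments and source labels. No coverage
  bias, indel errors, PCR duplicates or quality profiles are modeled —
  sufficient for diagnostic-site logic, not for general aligner testing.
* `simulate_population()` uses the Balding–Nichols model: ancestral
  frequencies uniform on `maf_range`, two subpopulations with
  Beta-distributed frequencies of variance fst·p(1−p), haploid Bernoulli
  draws, individuals split evenly.
* `simulate_phenotype()` draws `baseline + β·dosage + N(0, noise_sd)` and
  applies the saturation clamp. Defaults (baseline 59.1, SD 16.9 %L)
  reproduce the location and scale reported for a 738-male cohort.

Every generator is a pure function of its configuration and seed.

## Problem sizes and tolerances

The test suite checks, among others: Wilson-interval coverage ≥ 90% over
200 replicates at depth 500 (observed ≈ 94% with spaced sites); a single
depth-2000 estimate within 3 binomial SE of π_a = 0.87; type-I error in
[0.035, 0.065] over 200 null cohorts of 500 individuals × 200 variants;
and ≥ 90% CI coverage of a planted β = −18.54 at MAF 0.036 over 100
cohorts of 738 individuals. These sizes were chosen to give the binomial
checks enough resolution while keeping the default suite around two
minutes on one core; they are arguments in the tests, not limits of the
implementation.

## Known limitations

* The Wilson interval on pooled counts understates uncertainty when sites
  cluster within a read length (see above).
* The probe objective guarantees the published intervals are among its
  optima; the commercial probes' actual selection criteria are unknown.
* The ERG correction reproduces only the stated 1.5× weighting, not the
  upstream spectral-sensitivity fitting or its saturation nonlinearity.
* The association model is fixed-effects with eigenvector adjustment;
  strong cryptic relatedness beyond what eigenvectors capture would
  require a mixed model.
* Read simulation is substitution-only; pileup CIGAR handling is tested,
  but mapper-induced artifacts (multi-mapping between paralogs, soft-clip
  biases) are out of scope.
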