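# opsinquant

Paralog-specific opsin expression quantification and cone-ratio genetics.

The human long- (L, *OPN1LW*) and middle-wavelength (M, *OPN1MW*) cone
opsin genes sit side by side on the X chromosome and are ~96% identical at
the protein level and ~98% identical at the mRNA level. Standard probes
and read counting cannot tell them apart, yet the L:M cone ratio — which
varies enormously between people with normal color vision — is defined by
exactly this distinction. opsinquant implements the computational toolkit
for working at single-nucleotide resolution between the two paralogs:

* **Diagnostic sites** (`align_paralogs`, `find_diagnostic_sites`,
  `opsin_sites`): global alignment of a paralog pair, extraction of the
  positions where they differ, and transcript ↔ exon ↔ genome coordinate
  mapping, including the bundled 20-site table distinguishing the two
  opsin mRNAs.
* **Discriminating probe design** (`select_probe_pair`): chooses one
  window per paralog maximizing the diagnostic nucleotides both windows
  carry; on the opsin table it reproduces the published 40-nt M-opsin
  (902–941) / 42-nt L-opsin (880–921) probe pair with 8 differential
  nucleotides.
* **Diagnostic-site pileup quantification** (`pileup_at_sites`,
  `assign_site_counts`, `normalize_counts`, `estimate_mixture`): per-site
  allele counts from aligned reads, the normalized pileup statistic
  (counts per million total reads), and a pooled mixture estimate of the
  L:M expression fraction with a Wilson score interval.
* **Cone-ratio phenotypes** (`corrected_percent_L`): converts a
  flicker-photometric ERG L-signal fraction *s* into %L using the
  two-cone signal model with M cones weighted w = 1.5,
  `%L = 100·w·s / (1 + (w−1)·s)`.
* **Association scan** (`assoc_pipeline` and its stages): Freebayes-field
  record QC (QUAL > 10·AO, strand/placement support), MAF ≥ 3.5% and
  call-rate ≥ 90% filters, greedy LD pruning (r² < 0.75 in 100 kb
  windows), standardized-genotype kinship, eigenvector covariates,
  per-variant linear scan on haploid 0/1 dosages, Bonferroni correction.
* **Synthetic data** (`make_paralog_pair`, `simulate_reads`,
  `simulate_population`, `simulate_phenotype`): paralog pairs with
  planted differences, mixed-origin reads with substitution errors,
  Balding–Nichols structured haploid cohorts and %L phenotypes with a
  planted effect — all pure functions of (config, seed), so the whole
  pipeline runs and is tested without any external data.

## Worked example

```r
library(opsinquant)

## probe design on the bundled opsin diagnostic-site table
pp <- select_probe_pair(opsin_sites(), len_a = 42, len_b = 40)
pp
#> probe pair: a 880-921 (42 nt, 8 sites) / b 902-941 (40 nt, 8 sites)
#>   shared sites 8, union 8, overlap 40 nt

## quantify a simulated 87% L / 13% M mixture from reads
tr  <- make_paralog_pair(5000, 20, seed = 7, min_spacing = 150)
rd  <- simulate_reads(tr, pi_a = 0.87, depth = 2000, read_len = 75,
                      error_rate = 0.005, seed = 7)
est <- estimate_mixture(assign_site_counts(pileup_at_sites(rd, tr$sites),
                                           tr$sites))
est
#> paralog-a fraction 0.8694 (95% CI 0.8660-0.8727, n = 38526 informative bases)

## FP-ERG correction: equal L and M signal implies 60% L cones
corrected_percent_L(0.5, m_weight = 1.5)
#> [1] 60

## association scan on a simulated 738-male cohort with a planted effect
ps  <- simulate_population(738, 200, maf_range = c(0.05, 0.5), fst = 0.02,
                           seed = 7)
y   <- simulate_phenotype(ps$genotypes, causal_index = 100, beta = -18.54,
                          seed = 7)
out <- assoc_pipeline(ps$genotypes, y)
head(out$results[order(out$results$p_value), ], 3)
#>              id chrom    pos   beta   se  p_value passed_bonferroni
#> 100  chrX:99855  chrX  99855 -17.61 2.00 1.08e-17              TRUE
#> 98   chrX:97590  chrX  97590   5.65 1.80 1.80e-03             FALSE
#> 136 chrX:135397  chrX 135397   4.27 1.41 2.60e-03             FALSE
```

The probe pair is the published geometry (each window carries the 8
differential nucleotides of exon 5); the mixture estimate recovers the
simulated 87% L share from read pileups alone; and the scan flags exactly
the planted variant (true β = −18.54 %L per alt allele) at the
Bonferroni-corrected threshold while leaving background variants
non-significant.

## Documentation

The methods vignette
(`vignettes/opsin-paralog-quantification.Rmd`) describes the models,
parameter choices, numerical decisions and known limitations in detail.
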