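subset_variants_for_test <- function(G, keep) {
  genotype_matrix(G$dosage[, keep, drop = FALSE], G$chrom[keep], G$pos[keep],
                  G$ploidy)
}

random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    chrom = "chrX",
    pos = sample.int(5e5, n, replace = TRUE),
    ref = sample(c("A", "C"), n, replace = TRUE),
    alt = sample(c("G", "T"), n, replace = TRUE),
    qual = round(runif(n, 0, 300), 1),
    AO = sample(c(NA, 0:20), n, replace = TRUE),
    SAF = sample(c(NA, 0:10), n, replace = TRUE),
    SAR = sample(c(NA, 0:10), n, replace = TRUE),
    RPR = sample(c(NA, 0:10), n, replace = TRUE),
    RPL = sample(c(NA, 0:10), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

test_that("the Freebayes-field filter applies the published predicate", {
  rec <- data.frame(chrom = "chrX", pos = c(100, 200), ref = "A", alt = "G",
                    qual = c(100, 500), AO = c(5, 8), SAF = c(3, 0),
                    SAR = c(2, 8), RPR = c(2, 4), RPL = c(3, 4),
                    stringsAsFactors = FALSE)
  kept <- filter_variant_calls(rec)
  expect_identical(kept$pos, 100)                   # 100 > 10*5, all supports ok
  expect_identical(attr(kept, "rejections")$reason, "alt strand support")

  low <- rec[1, ]; low$qual <- 50                   # exactly 10*AO: not greater
  expect_identical(nrow(filter_variant_calls(low)), 0L)
})

test_that("filter survivors equal independent per-record evaluation", {
  rec <- random_records(300, seed = 17)
  kept <- filter_variant_calls(rec)
  seen <- character(0)
  oracle_keep <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    oracle_keep[i] <- oracle_filter_keep(rec[i, ], seen)
    if (oracle_keep[i])
      seen <- c(seen, paste(rec$chrom[i], rec$pos[i], rec$ref[i], rec$alt[i]))
  }
  expect_equal(kept$pos, rec$pos[oracle_keep])
  expect_equal(nrow(kept) + nrow(attr(kept, "rejections")), nrow(rec))
})

test_that("filtering is idempotent", {
  rec <- random_records(200, seed = 23)
  once <- filter_variant_calls(rec)
  twice <- filter_variant_calls(once)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
})

test_that("MAF and call-rate filters match brute-force column computation", {
  doso <- cbind(c(rep(1, 3), rep(0, 97)),           # MAF 0.03: dropped
                c(rep(1, 10), rep(0, 90)),          # MAF 0.10: kept
                c(rep(NA, 11), rep(1, 44), rep(0, 45)))  # 89% called: dropped
  G <- genotype_matrix(doso, rep("chrX", 3), c(10, 20, 30), ploidy = 1)
  Gf <- filter_by_maf_callrate(G)
  expect_identical(Gf$pos, 20)

  set.seed(31)
  n <- 80; m <- 60
  d <- matrix(rbinom(n * m, 1, 0.2), n, m)
  d[sample(length(d), 400)] <- NA
  G2 <- genotype_matrix(d, rep("chr1", m), seq_len(m) * 100, ploidy = 1)
  G2f <- filter_by_maf_callrate(G2)
  keep <- vapply(seq_len(m), function(j) {
    x <- d[, j]; x <- x[!is.na(x)]
    p <- mean(x)
    min(p, 1 - p) >= 0.035 && mean(!is.na(d[, j])) >= 0.90
  }, logical(1))
  expect_identical(ncol(G2f$dosage), sum(keep))
  expect_equal(G2f$pos, (seq_len(m) * 100)[keep])
  # idempotent
  expect_identical(ncol(filter_by_maf_callrate(G2f)$dosage), sum(keep))
})

test_that("LD pruning keeps the leftmost of correlated variants within the window", {
  set.seed(41)
  x <- rbinom(100, 1, 0.4)
  y <- rbinom(100, 1, 0.4)
  G <- genotype_matrix(cbind(x, x, y), rep("chrX", 3), c(1000, 1001, 2000),
                       ploidy = 1)
  kept <- ld_prune(G)
  expect_identical(kept, c(1L, 3L))                 # duplicate 1 bp away dropped

  Gfar <- genotype_matrix(cbind(x, x), rep("chrX", 2), c(1000, 150000),
                          ploidy = 1)
  expect_identical(ld_prune(Gfar), c(1L, 2L))       # r2 = 1 but outside window
  expect_error(ld_prune(genotype_matrix(cbind(x, y), rep("chrX", 2),
                                        c(2000, 1000), ploidy = 1)), "sorted")
})

test_that("no kept pair within the window violates the r2 cutoff (audit)", {
  set.seed(47)
  n <- 150; m <- 120
  base <- matrix(rbinom(n * 12, 1, 0.3), n, 12)
  # blocks of correlated variants: noisy copies of 12 founders
  d <- sapply(seq_len(m), function(j) {
    src <- base[, (j - 1) %/% 10 + 1]
    flip <- rbinom(n, 1, 0.08)
    ifelse(flip == 1, 1 - src, src)
  })
  G <- genotype_matrix(d, rep("chrX", m), cumsum(sample(500:1500, m, TRUE)),
                       ploidy = 1)
  cfg <- assoc_config()
  kept <- ld_prune(G, cfg)
  for (a in seq_along(kept)) {
    for (b in seq_len(a - 1L)) {
      j <- kept[a]; k <- kept[b]
      if (G$pos[j] - G$pos[k] <= cfg$ld_window_bp) {
        r2 <- cor(d[, j], d[, k])^2
        expect_lt(r2, cfg$ld_r2_max)
      }
    }
  }
  # idempotent: pruning the pruned set keeps everything
  expect_identical(ld_prune(subset_variants_for_test(G, kept), cfg),
                   seq_along(kept))
})

test_that("kinship is a standardized Gram matrix with GRM expectations", {
  d <- rbind(c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1), c(0, 1, 0, 1, 0))
  G <- genotype_matrix(d, rep("chrX", 5), 1:5 * 1000, ploidy = 1)
  K <- compute_kinship(G)
  expect_equal(K[1, 2], K[1, 1])                    # identical genotypes
  expect_equal(K, t(K))
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values > -1e-8))

  mono <- genotype_matrix(cbind(d, 1), rep("chrX", 6), 1:6 * 1000, ploidy = 1)
  expect_warning(compute_kinship(mono), "monomorphic")

  ps <- simulate_population(100, 5000, maf_range = c(0.1, 0.5), fst = 0,
                            seed = 53)
  K2 <- compute_kinship(ps$genotypes)
  offdiag <- K2[upper.tri(K2)]
  expect_lt(abs(mean(offdiag)), 0.05)
  expect_lt(abs(mean(diag(K2)) - 1), 0.05)
})

test_that("eigenvectors are orthonormal, match an SVD oracle, and recover structure", {
  ps <- simulate_population(120, 800, fst = 0.05, seed = 59)
  K <- suppressWarnings(compute_kinship(ps$genotypes))  # drift can fix a variant
  V <- compute_eigenvectors(K, 5)
  expect_equal(crossprod(V), diag(5), tolerance = 1e-8)
  # leading eigenvector against an independent dense decomposition (SVD)
  sv <- svd(K)
  expect_equal(abs(sum(V[, 1] * sv$u[, 1])), 1, tolerance = 1e-6)
  # full agreement on a PSD matrix with well-separated spectrum
  set.seed(60)
  A <- crossprod(matrix(rnorm(60 * 15), 60, 15)) / 60
  VA <- compute_eigenvectors(A, 5)
  svA <- svd(A)
  for (j in 1:5)
    expect_equal(abs(sum(VA[, j] * svA$u[, j])), 1, tolerance = 1e-6)
  grp <- ps$subpop - 1
  r <- cor(V[, 1], grp)
  expect_gt(abs(r), 0.9)
  expect_error(compute_eigenvectors(K, nrow(K)), "smaller")
})

test_that("the scan is algebraically identical to per-variant lm fits", {
  ps <- simulate_population(60, 8, maf_range = c(0.2, 0.5), seed = 61)
  G <- ps$genotypes
  G$dosage[1:3, 2] <- NA                            # exercise mean imputation
  y <- simulate_phenotype(G, causal_index = 4, beta = -10, seed = 61)
  cov <- matrix(rnorm(120), 60, 2)
  res <- scan_association(G, y, cov)
  for (j in seq_len(8)) {
    x <- G$dosage[, j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    fit <- summary(lm(y ~ x + cov))$coefficients
    expect_equal(res$beta[j], fit["x", "Estimate"], tolerance = 1e-10)
    expect_equal(res$se[j], fit["x", "Std. Error"], tolerance = 1e-10)
    expect_equal(res$p_value[j], fit["x", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("signal absorbed by a covariate gives null effects and collinear dosages are skipped", {
  ps <- simulate_population(80, 10, maf_range = c(0.2, 0.5), seed = 67)
  y <- rnorm(80)
  res <- scan_association(ps$genotypes, y, covariates = cbind(y))
  expect_true(all(abs(res$beta) < 1e-8))
  expect_true(all(res$p_value > 0.999))

  # a dosage equal to a covariate has no residual variance: skipped
  G <- ps$genotypes
  cov2 <- cbind(G$dosage[, 1])
  res2 <- scan_association(G, rnorm(80), covariates = cov2)
  expect_true(is.na(res2$beta[1]))
  expect_identical(attr(res2, "skipped")$id, G$id[1])
})

test_that("permuted phenotypes give uniform p-values", {
  ps <- simulate_population(300, 2000, maf_range = c(0.1, 0.5), seed = 71)
  y <- simulate_phenotype(ps$genotypes, seed = 71)
  res <- scan_association(ps$genotypes, sample(y), cfg = assoc_config())
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Bonferroni thresholds are alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 2890), 3), 1.73e-5)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("the full cascade flags a strong planted variant and is reproducible", {
  ps <- simulate_population(400, 150, maf_range = c(0.05, 0.5), fst = 0.02,
                            seed = 73)
  y <- simulate_phenotype(ps$genotypes, causal_index = 75, beta = -18.54,
                          seed = 73)
  out <- assoc_pipeline(ps$genotypes, y)
  causal_id <- ps$genotypes$id[75]
  row <- out$results[out$results$id == causal_id, ]
  expect_identical(nrow(row), 1L)
  expect_lt(row$p_value, attr(out$results, "bonferroni_threshold"))
  expect_lt(row$beta, 0)
  out2 <- assoc_pipeline(ps$genotypes, y)
  expect_equal(out$results$p_value, out2$results$p_value)
})
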