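#' Association-scan configuration
#'
#' Defaults follow the targeted-sequencing analysis this package implements:
#' minor allele frequency >= 3.5%, per-variant call rate >= 90%, greedy LD
#' pruning at r^2 < 0.75 within 100 kb windows, 5 genotype eigenvectors as
#' covariates, and family-wise alpha 0.05 with Bonferroni correction.
#'
#' @param maf_min Minimum minor allele frequency.
#' @param callrate_min Minimum per-variant genotyping rate.
#' @param ld_r2_max Squared-correlation pruning cutoff (a variant is dropped
#'   when r^2 with a kept variant within the window reaches this value).
#' @param ld_window_bp LD window in bp.
#' @param n_eigenvectors Number of kinship eigenvectors used as covariates.
#' @param alpha Family-wise significance level.
#' @param qual_rule Reading of the Freebayes quality filter: `"qual_gt_10_ao"`
#'   (QUAL > 10 x AO, the conventional quality-per-alt-observation rule,
#'   default) or `"qual_gt_10_dp_ro"` (QUAL > 10 x (DP - RO)).
#' @param strand_min,place_min Minimum alt reads per strand and per placement
#'   side (default 1 each; set 2 for the stricter reading).
#' @param ao_min Minimum alt observations (default 2).
#' @return A list of class `assoc_config`.
#' @export
assoc_config <- function(maf_min = 0.035, callrate_min = 0.90,
                         ld_r2_max = 0.75, ld_window_bp = 1e5,
                         n_eigenvectors = 5, alpha = 0.05,
                         qual_rule = c("qual_gt_10_ao", "qual_gt_10_dp_ro"),
                         strand_min = 1, place_min = 1, ao_min = 2) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, callrate_min >= 0, callrate_min <= 1,
            ld_r2_max >= 0, ld_r2_max <= 1, ld_window_bp > 0,
            n_eigenvectors >= 0, alpha > 0, alpha <= 1)
  structure(list(maf_min = maf_min, callrate_min = callrate_min,
                 ld_r2_max = ld_r2_max, ld_window_bp = ld_window_bp,
                 n_eigenvectors = n_eigenvectors, alpha = alpha,
                 qual_rule = match.arg(qual_rule),
                 strand_min = strand_min, place_min = place_min,
                 ao_min = ao_min),
            class = "assoc_config")
}

#' Filter Freebayes-dialect variant records
#'
#' Applies the site-quality cascade used upstream of the association scan:
#' QUAL greater than 10 times the alt observations, at least one alt read on
#' each strand (SAF, SAR), at least one alt read placed on each side (RPL,
#' RPR), and at least two alt observations overall; duplicate
#' (chrom, pos, ref, alt) records are removed keeping the first.  Records
#' missing a required INFO field are rejected, with the reason recorded.
#'
#' @param records A data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `AO`, `SAF`, `SAR`, `RPR`, `RPL` (and `DP`, `RO` for the
#'   alternative quality rule).
#' @param cfg An [assoc_config()].
#' @return The surviving records, with a `rejections` attribute: a data frame
#'   of dropped rows and the first reason each failed.
#' @export
filter_variant_calls <- function(records, cfg = assoc_config()) {
  req <- c("chrom", "pos", "ref", "alt", "qual", "AO", "SAF", "SAR", "RPR", "RPL")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  note <- function(bad, why) reason[is.na(reason) & bad] <<- why
  info <- c("AO", "SAF", "SAR", "RPR", "RPL",
            if (cfg$qual_rule == "qual_gt_10_dp_ro") c("DP", "RO"))
  for (f in intersect(info, names(records)))
    note(is.na(records[[f]]), paste0("missing ", f))
  note(is.na(records$qual), "missing qual")
  qual_ref <- if (cfg$qual_rule == "qual_gt_10_ao") records$AO
              else records$DP - records$RO
  note(!(records$qual > 10 * qual_ref), "qual <= 10x alt observations")
  note(records$SAF < cfg$strand_min | records$SAR < cfg$strand_min,
       "alt strand support")
  note(records$RPR < cfg$place_min | records$RPL < cfg$place_min,
       "alt placement balance")
  note(records$AO < cfg$ao_min, "too few alt observations")
  key <- paste(records$chrom, records$pos, records$ref, records$alt)
  note(duplicated(key), "duplicate record")
  kept <- records[is.na(reason), , drop = FALSE]
  rej <- records[!is.na(reason), , drop = FALSE]
  rej$reason <- reason[!is.na(reason)]
  attr(kept, "rejections") <- rej
  kept
}

#' Genotype matrices
#'
#' A light container for a cohort's dosages: an individuals x variants
#' numeric matrix (`NA` = missing call) plus per-variant `chrom`/`pos` and a
#' ploidy.  Haploid dosages (male X, ploidy 1) are 0/1; diploid 0/1/2.
#'
#' @param dosage Individuals x variants matrix.
#' @param chrom,pos Per-variant chromosome and 1-based position
#'   (position-sorted within chromosome).
#' @param ploidy 1 or 2.
#' @param id Optional variant ids (default `chrom:pos`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, chrom, pos, ploidy = 1, id = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(length(chrom) == ncol(dosage), length(pos) == ncol(dosage),
            ploidy %in% c(1, 2))
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && (any(vals < 0) || any(vals > ploidy) ||
                       any(vals != round(vals))))
    stop("dosages must be integers in [0, ploidy] or NA", call. = FALSE)
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  colnames(dosage) <- id
  structure(list(dosage = dosage, chrom = as.character(chrom),
                 pos = as.numeric(pos), ploidy = ploidy, id = id),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants, ploidy %d, %.1f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), x$ploidy,
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

subset_variants <- function(G, keep) {
  genotype_matrix(G$dosage[, keep, drop = FALSE], G$chrom[keep], G$pos[keep],
                  G$ploidy, G$id[keep])
}

#' Per-variant allele frequency, MAF and call rate
#'
#' @param G A [genotype_matrix()].
#' @return A data frame `id`, `chrom`, `pos`, `freq` (alt-allele frequency on
#'   non-missing alleles, respecting ploidy), `maf`, `callrate`.
#' @export
variant_stats <- function(G) {
  p <- colMeans(G$dosage, na.rm = TRUE) / G$ploidy
  p[is.nan(p)] <- NA_real_
  data.frame(id = G$id, chrom = G$chrom, pos = G$pos, freq = p,
             maf = pmin(p, 1 - p),
             callrate = colMeans(!is.na(G$dosage)),
             stringsAsFactors = FALSE)
}

#' Filter variants by MAF and call rate
#'
#' @param G A [genotype_matrix()].
#' @param cfg An [assoc_config()].
#' @return The filtered `genotype_matrix`.
#' @export
filter_by_maf_callrate <- function(G, cfg = assoc_config()) {
  if (ncol(G$dosage) == 0L) stop("empty genotype matrix", call. = FALSE)
  st <- variant_stats(G)
  keep <- !is.na(st$maf) & st$maf >= cfg$maf_min &
    st$callrate >= cfg$callrate_min
  subset_variants(G, keep)
}

#' Greedy windowed LD pruning
#'
#' Scans variants left to right (they must be position-sorted within
#' chromosome) and keeps a variant unless its squared Pearson dosage
#' correlation with an already-kept variant within `ld_window_bp` reaches
#' `ld_r2_max`.  The left-most variant of a correlated set is therefore
#' retained.
#'
#' @param G A [genotype_matrix()].
#' @param cfg An [assoc_config()].
#' @return Integer indices of kept variants (use [subset_variants] semantics
#'   via `ld_prune_matrix` to get the pruned matrix directly).
#' @export
ld_prune <- function(G, cfg = assoc_config()) {
  m <- ncol(G$dosage)
  ord <- order(G$chrom, G$pos)
  if (any(ord != seq_len(m)))
    stop("variants must be position-sorted within chromosome", call. = FALSE)
  kept <- integer(0)
  for (j in seq_len(m)) {
    near <- kept[G$chrom[kept] == G$chrom[j] &
                   G$pos[j] - G$pos[kept] <= cfg$ld_window_bp]
    drop <- FALSE
    for (k in rev(near)) {
      r <- suppressWarnings(stats::cor(G$dosage[, j], G$dosage[, k],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 >= cfg$ld_r2_max) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, j)
  }
  kept
}

#' @rdname ld_prune
#' @export
ld_prune_matrix <- function(G, cfg = assoc_config()) {
  subset_variants(G, ld_prune(G, cfg))
}

impute_and_standardize <- function(G, drop_monomorphic = TRUE) {
  X <- G$dosage
  p <- colMeans(X, na.rm = TRUE) / G$ploidy
  mono <- is.na(p) | p <= 0 | p >= 1
  if (any(mono)) {
    if (drop_monomorphic)
      warning(sum(mono), " monomorphic variant(s) excluded", call. = FALSE)
    X <- X[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  mu <- G$ploidy * p
  sdv <- sqrt(G$ploidy * p * (1 - p))
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mu[j]
  }
  sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
}

#' Standardized-genotype kinship matrix
#'
#' The genetic relationship matrix `K = X X' / m`, where column j of X is the
#' mean-imputed dosage centered by `ploidy * p_j` and scaled by
#' `sqrt(ploidy * p_j (1 - p_j))` (i.e. uniform variant weights and a
#' frequency power of -1).  Monomorphic variants carry no information and are
#' excluded with a warning.
#'
#' @param G A filtered, pruned [genotype_matrix()].
#' @return A symmetric positive semi-definite n x n matrix.
#' @export
compute_kinship <- function(G) {
  X <- impute_and_standardize(G)
  if (ncol(X) == 0L) stop("no polymorphic variants", call. = FALSE)
  K <- tcrossprod(X) / ncol(X)
  (K + t(K)) / 2
}

#' Top kinship eigenvectors
#'
#' Orthonormal eigenvectors of the kinship matrix, ordered by decreasing
#' eigenvalue, used as covariates against population stratification.  Signs
#' follow the convention that each vector's largest-magnitude entry is
#' positive.
#'
#' @param K Symmetric kinship matrix.
#' @param n Number of eigenvectors (default 5; must be < nrow(K)).
#' @return An nrow(K) x n matrix with eigenvalues in attribute `"values"`.
#' @export
compute_eigenvectors <- function(K, n = 5) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (n >= nrow(K))
    stop("n must be smaller than the number of individuals", call. = FALSE)
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric", call. = FALSE)
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  V <- e$vectors[, seq_len(n), drop = FALSE]
  for (j in seq_len(n)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  attr(V, "values") <- e$values[seq_len(n)]
  V
}

#' Per-variant association scan
#'
#' For each variant, fits the fixed-effects linear model
#' `phenotype ~ intercept + dosage + covariates` and reports the dosage
#' effect `beta`, its standard error, the two-sided t-test p-value, and a
#' Bonferroni flag at `alpha / m` where m is the number of variants actually
#' tested.  Missing dosages are mean-imputed; variants collinear with the
#' covariates are skipped with a reason.  Covariates are projected out once,
#' so the scan is a single pass of simple regressions on residualized
#' dosages -- algebraically identical to per-variant `lm()` fits.
#'
#' @param G A [genotype_matrix()].
#' @param phenotype Numeric vector, one value per individual, no missing.
#' @param covariates Optional numeric matrix of covariates (e.g.
#'   [compute_eigenvectors()] output); an intercept is always included.
#' @param cfg An [assoc_config()] (supplies `alpha`).
#' @return A data frame of class `assoc_result`: `id`, `chrom`, `pos`,
#'   `beta`, `se`, `p_value`, `passed_bonferroni`, with attributes
#'   `"bonferroni_threshold"`, `"n_tested"` and `"skipped"`.
#' @export
scan_association <- function(G, phenotype, covariates = NULL,
                             cfg = assoc_config()) {
  n <- nrow(G$dosage)
  if (length(phenotype) != n)
    stop("phenotype length must match the number of individuals", call. = FALSE)
  if (anyNA(phenotype)) stop("phenotype must not contain NA", call. = FALSE)
  C <- cbind(intercept = rep(1, n), covariates)
  qr_C <- qr(C)
  if (qr_C$rank < ncol(C))
    stop("covariates are collinear with each other or the intercept",
         call. = FALSE)
  resid_y <- qr.resid(qr_C, phenotype)
  # phenotype fully absorbed by the covariates: every effect is exactly null
  if (sum(resid_y^2) < 1e-12 * max(sum(phenotype^2), 1))
    resid_y <- rep(0, n)
  X <- G$dosage
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mu[j]
  }
  resid_X <- qr.resid(qr_C, X)
  xx <- colSums(resid_X^2)
  df <- n - qr_C$rank - 1L
  if (df < 1L) stop("not enough individuals for the model", call. = FALSE)
  testable <- xx > 1e-10 * n
  beta <- se <- p <- rep(NA_real_, ncol(X))
  xy <- as.numeric(crossprod(resid_X, resid_y))
  beta[testable] <- xy[testable] / xx[testable]
  rss <- sum(resid_y^2) - beta^2 * xx
  sigma2 <- pmax(rss, 0) / df
  se[testable] <- sqrt(sigma2[testable] / xx[testable])
  tstat <- ifelse(se > 0, beta / se, 0)  # zero-residual fit: null effect
  p[testable] <- 2 * stats::pt(abs(tstat[testable]), df, lower.tail = FALSE)
  m_tested <- sum(testable)
  if (m_tested == 0L) stop("no testable variants", call. = FALSE)
  thr <- bonferroni_threshold(cfg$alpha, m_tested)
  out <- data.frame(id = G$id, chrom = G$chrom, pos = G$pos,
                    beta = beta, se = se, p_value = p,
                    passed_bonferroni = !is.na(p) & p < thr,
                    stringsAsFactors = FALSE)
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "n_tested") <- m_tested
  attr(out, "skipped") <- data.frame(
    id = G$id[!testable],
    reason = rep("collinear with covariates", sum(!testable)),
    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  alpha / m
}

#' Full association cascade
#'
#' Chains the scan stages on an already-genotyped matrix: MAF/call-rate
#' filter, windowed LD pruning, kinship, eigenvector covariates, per-variant
#' scan with Bonferroni flags.
#'
#' @param G A [genotype_matrix()] (position-sorted).
#' @param phenotype Numeric phenotype (%L), one value per individual.
#' @param cfg An [assoc_config()].
#' @return A list: `genotypes` (pruned matrix), `kinship`, `eigenvectors`,
#'   `results` (the [scan_association()] table).
#' @export
assoc_pipeline <- function(G, phenotype, cfg = assoc_config()) {
  G2 <- filter_by_maf_callrate(G, cfg)
  G3 <- ld_prune_matrix(G2, cfg)
  K <- compute_kinship(G3)
  V <- if (cfg$n_eigenvectors > 0)
    compute_eigenvectors(K, cfg$n_eigenvectors) else NULL
  res <- scan_association(G3, phenotype, V, cfg)
  list(genotypes = G3, kinship = K, eigenvectors = V, results = res)
}

#' Write association results as TSV
#'
#' @param results An `assoc_result` data frame.
#' @param path Output path.
#' @export
write_assoc_results <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
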