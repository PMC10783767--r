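# Independent oracles used across the suite.  These deliberately use naive
# position-by-position loops, not the package's own code paths.

# diagnostic sites by direct scan of two equal-length ungapped sequences
oracle_diff_sites <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  stopifnot(length(a) == length(b))
  pos <- integer(0)
  for (i in seq_along(a)) {
    if (a[i] != b[i] && a[i] != "N" && b[i] != "N") pos <- c(pos, i)
  }
  data.frame(base_a = a[pos], base_b = b[pos], pos_a = pos, pos_b = pos,
             stringsAsFactors = FALSE)
}

# interval-membership count of sites per window start
oracle_window_counts <- function(pos, transcript_len, len) {
  starts <- seq_len(transcript_len - len + 1L)
  vapply(starts, function(s) {
    n <- 0L
    for (p in pos) if (p >= s && p <= s + len - 1L) n <- n + 1L
    n
  }, integer(1))
}

# exhaustive probe-pair search over every start pair, same objective as
# select_probe_pair (shared sites, then union), overlap via the same
# site-anchored offset; returns the best (shared, union) objective
oracle_best_pair_objective <- function(sites, len_a, len_b, tlen_a, tlen_b) {
  nearest_offset <- function(pb) {
    i <- which.min(abs(sites$pos_b - pb))
    sites$pos_a[i] - sites$pos_b[i]
  }
  best <- c(-1L, -1L)
  for (sa in seq_len(tlen_a - len_a + 1L)) {
    A <- which(sites$pos_a >= sa & sites$pos_a <= sa + len_a - 1L)
    for (sb in seq_len(tlen_b - len_b + 1L)) {
      B <- which(sites$pos_b >= sb & sites$pos_b <= sb + len_b - 1L)
      off <- nearest_offset(sb + (len_b - 1) / 2)
      ov <- min(sa + len_a - 1L, sb + len_b - 1L + off) - max(sa, sb + off) + 1L
      if (ov < 1L) next
      key <- c(length(intersect(A, B)), length(union(A, B)))
      if (key[1] > best[1] || (key[1] == best[1] && key[2] > best[2]))
        best <- key
    }
  }
  best
}

# per-record re-implementation of the Freebayes-field filter predicate
oracle_filter_keep <- function(rec, seen_keys) {
  fields <- c("qual", "AO", "SAF", "SAR", "RPR", "RPL")
  for (f in fields) if (is.na(rec[[f]])) return(FALSE)
  key <- paste(rec$chrom, rec$pos, rec$ref, rec$alt)
  if (key %in% seen_keys) return(FALSE)
  rec$qual > 10 * rec$AO && rec$SAF >= 1 && rec$SAR >= 1 &&
    rec$RPR >= 1 && rec$RPL >= 1 && rec$AO >= 2
}

# Hudson Fst estimator from subpopulation allele counts (haploid)
oracle_hudson_fst <- function(dosage, subpop) {
  n1 <- sum(subpop == 1); n2 <- sum(subpop == 2)
  p1 <- colMeans(dosage[subpop == 1, , drop = FALSE])
  p2 <- colMeans(dosage[subpop == 2, , drop = FALSE])
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# equal-width decile binning by direct loop
oracle_decile_freq <- function(percent_L, genotype, n_bins = 10) {
  breaks <- seq(0, 100, length.out = n_bins + 1)
  geno <- sort(unique(genotype))
  freq <- matrix(0, n_bins, length(geno), dimnames = list(NULL, geno))
  n <- integer(n_bins)
  for (i in seq_along(percent_L)) {
    b <- NA
    for (k in seq_len(n_bins)) {
      lo <- breaks[k]; hi <- breaks[k + 1]
      if ((percent_L[i] > lo || k == 1) && percent_L[i] >= lo &&
          percent_L[i] <= hi) b <- k
    }
    n[b] <- n[b] + 1L
    freq[b, genotype[i]] <- freq[b, genotype[i]] + 1
  }
  list(n = n, freq = sweep(freq, 1, pmax(n, 1), "/"))
}

# build a site table without going through find_diagnostic_sites
make_sites <- function(pos_a, pos_b = pos_a, base_a = NULL, base_b = NULL) {
  m <- length(pos_a)
  if (is.null(base_a)) base_a <- rep(c("A", "C"), length.out = m)
  if (is.null(base_b)) base_b <- rep(c("G", "T"), length.out = m)
  df <- data.frame(exon = rep(NA_character_, m), base_a = base_a,
                   base_b = base_b, pos_a = as.integer(pos_a),
                   pos_b = as.integer(pos_b),
                   exon_pos = rep(NA_integer_, m),
                   genome_pos_a = rep(NA_real_, m),
                   genome_pos_b = rep(NA_real_, m),
                   stringsAsFactors = FALSE)
  class(df) <- c("diagnostic_sites", "data.frame")
  df
}

# site_base_counts row constructor for direct assign_site_counts tests
make_base_counts <- function(pos, A = 0L, C = 0L, G = 0L, T = 0L, N = 0L) {
  df <- data.frame(pos = pos, n_A = as.integer(A), n_C = as.integer(C),
                   n_G = as.integer(G), n_T = as.integer(T), n_N = as.integer(N))
  df$depth <- df$n_A + df$n_C + df$n_G + df$n_T + df$n_N
  class(df) <- c("site_base_counts", "data.frame")
  df
}
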