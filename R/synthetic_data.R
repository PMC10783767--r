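#' Simulate a paralog pair with planted diagnostic sites
#'
#' Draws a random DNA sequence and substitutes `n_diffs` uniformly placed
#' positions (each to a different base) to create its paralog, mirroring a
#' near-identical gene pair such as the 20-site opsin pair.  Because the
#' differences are substitution-only, the two sequences share one coordinate
#' frame (`pos_a == pos_b` for every planted site).
#'
#' @param length Sequence length (nt).
#' @param n_diffs Number of planted differences (`<= length`).
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @param gc GC content of the random background (default 0.5).
#' @param min_spacing Minimum distance between planted sites (default 1:
#'   unconstrained uniform placement).  Setting it above the read length
#'   guarantees each simulated read overlaps at most one site, the regime in
#'   which pooled allele counts are independent.
#' @return A list of class `paralog_sim`: `seq_a`, `seq_b` (character),
#'   `sites` (a `diagnostic_sites` table of the planted differences), `seed`.
#' @export
make_paralog_pair <- function(length, n_diffs, seed = 1, gc = 0.5,
                              min_spacing = 1) {
  stopifnot(length >= 1, n_diffs >= 0, n_diffs <= length, min_spacing >= 1)
  if (n_diffs > 0 && length - (n_diffs - 1) * (min_spacing - 1) < n_diffs)
    stop("n_diffs sites cannot fit at the requested min_spacing", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  a <- sample(names(probs), length, replace = TRUE, prob = probs)
  b <- a
  pos <- if (n_diffs == 0) integer(0) else {
    gap <- min_spacing - 1L
    raw <- sort(sample.int(length - (n_diffs - 1L) * gap, n_diffs))
    raw + gap * (seq_len(n_diffs) - 1L)
  }
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), a[p]), 1L)
  sites <- new_site_table(data.frame(
    base_a = a[pos], base_b = b[pos], pos_a = pos, pos_b = pos,
    stringsAsFactors = FALSE))
  structure(list(seq_a = paste(a, collapse = ""),
                 seq_b = paste(b, collapse = ""),
                 sites = sites, seed = seed),
            class = "paralog_sim")
}

#' Simulate reads from a two-paralog mixture
#'
#' Each read is drawn from paralog a with probability `pi_a`, starts
#' uniformly along its source, and receives iid substitution errors at rate
#' `error_rate` (no indels).  Reads are emitted with their true alignment
#' (start position, implicit all-match CIGAR) and source label, so the
#' pileup stage is testable without a mapper.  Base qualities are uniform
#' Q40.
#'
#' @param truth A [make_paralog_pair()] result.
#' @param pi_a Mixture proportion of paralog a in \[0, 1\].
#' @param depth Target mean per-base coverage; the number of reads is
#'   `round(depth * length / read_len)`.
#' @param read_len Read length (<= sequence length).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A reads data frame (columns `read_id`, `source`, `start`, `seq`,
#'   `qual`) usable directly by [pileup_at_sites()].
#' @export
simulate_reads <- function(truth, pi_a, depth, read_len,
                           error_rate = 0, seed = 1) {
  stopifnot(inherits(truth, "paralog_sim"), pi_a >= 0, pi_a <= 1,
            depth > 0, read_len >= 1, error_rate >= 0, error_rate < 1)
  L <- nchar(truth$seq_a)
  if (read_len > L) stop("read_len exceeds sequence length", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_reads <- max(1L, as.integer(round(depth * L / read_len)))
  src_a <- stats::runif(n_reads) < pi_a
  starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
  seqs <- ifelse(src_a,
                 substring(truth$seq_a, starts, starts + read_len - 1L),
                 substring(truth$seq_b, starts, starts + read_len - 1L))
  if (error_rate > 0) {
    n_err <- stats::rbinom(n_reads, read_len, error_rate)
    for (r in which(n_err > 0L)) {
      at <- sample.int(read_len, n_err[r])
      for (p in at) {
        orig <- substr(seqs[r], p, p)
        substr(seqs[r], p, p) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
      }
    }
  }
  data.frame(read_id = sprintf("read_%06d", seq_len(n_reads)),
             source = ifelse(src_a, "a", "b"),
             start = starts, seq = seqs,
             qual = strrep("I", read_len),
             stringsAsFactors = FALSE)
}

#' Export simulated reads as FASTQ (plus a truth table)
#'
#' @param reads A [simulate_reads()] result.
#' @param fastq_path Output FASTQ path.
#' @param truth_path Optional TSV path for the per-read truth
#'   (id, source, start).
#' @export
write_reads_fastq <- function(reads, fastq_path, truth_path = NULL) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  q <- Biostrings::PhredQuality(reads$qual)
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(x, q), fastq_path)
  if (!is.null(truth_path))
    utils::write.table(reads[, c("read_id", "source", "start")], truth_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fastq_path)
}

#' Simulate a structured haploid cohort
#'
#' Balding-Nichols two-subpopulation model: per-variant ancestral frequencies
#' are drawn uniformly from `maf_range`; with `fst > 0` each subpopulation's
#' frequency is Beta-distributed around the ancestral value with variance
#' `fst * p * (1 - p)`; haploid (male-X) dosages are then Bernoulli draws.
#' Individuals split evenly between the two subpopulations.
#'
#' @param n_individuals,n_variants Cohort dimensions.
#' @param maf_range Ancestral allele-frequency range, within (0, 0.5\].
#' @param fst Fixation index between the two subpopulations, in \[0, 1).
#' @param spacing_bp Mean spacing between adjacent variants (positions are
#'   cumulative uniform gaps on one chromosome).
#' @param chrom Chromosome label (default `"chrX"`).
#' @param seed Integer seed.
#' @return A list of class `pop_sim`: `genotypes` (haploid
#'   [genotype_matrix()]), `subpop` (1/2 labels), `p_ancestral`, `p_subpop`
#'   (2 x m matrix).
#' @export
simulate_population <- function(n_individuals, n_variants,
                                maf_range = c(0.05, 0.5), fst = 0,
                                spacing_bp = 1000, chrom = "chrX", seed = 1) {
  stopifnot(n_individuals >= 2, n_variants >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, fst >= 0, fst < 1)
  if (!is.null(seed)) set.seed(seed)
  p_anc <- stats::runif(n_variants, maf_range[1], maf_range[2])
  p_sub <- if (fst > 0) {
    shape <- (1 - fst) / fst
    rbind(stats::rbeta(n_variants, p_anc * shape, (1 - p_anc) * shape),
          stats::rbeta(n_variants, p_anc * shape, (1 - p_anc) * shape))
  } else {
    rbind(p_anc, p_anc)
  }
  rownames(p_sub) <- NULL
  subpop <- rep(1:2, length.out = n_individuals)
  probs <- p_sub[subpop, , drop = FALSE]
  dosage <- matrix(stats::rbinom(n_individuals * n_variants, 1L,
                                 as.vector(probs)),
                   nrow = n_individuals)
  rownames(dosage) <- sprintf("S%04d", seq_len(n_individuals))
  pos <- cumsum(ceiling(stats::runif(n_variants, 0.5, 1.5) * spacing_bp))
  structure(list(
    genotypes = genotype_matrix(dosage, rep(chrom, n_variants), pos,
                                ploidy = 1),
    subpop = subpop, p_ancestral = p_anc, p_subpop = p_sub, seed = seed),
    class = "pop_sim")
}

#' Simulate a %L phenotype with an optional planted variant effect
#'
#' `y = baseline + beta * dosage + N(0, noise_sd)`, then clamped to
#' \[0, 110\] and values above 100 set to 100, emulating the saturation
#' behaviour of FP-ERG-derived %L.  Defaults reproduce the cohort location
#' and scale (mean 59.1%, SD 16.9%) observed in 738 males.
#'
#' @param G A [genotype_matrix()].
#' @param causal_index Column index of the causal variant, or `NULL` for a
#'   null phenotype.
#' @param beta Effect per alt allele, in %L units (on the haploid 0/1 dosage
#'   scale).
#' @param baseline,noise_sd Phenotype location and residual SD (%L units).
#' @param clamp Apply the saturation clamp (default TRUE).
#' @param seed Integer seed.
#' @return Numeric %L vector, one value per individual.
#' @export
simulate_phenotype <- function(G, causal_index = NULL, beta = 0,
                               baseline = 59.1, noise_sd = 16.9,
                               clamp = TRUE, seed = 1) {
  n <- nrow(G$dosage)
  if (!is.null(seed)) set.seed(seed)
  y <- baseline + stats::rnorm(n, 0, noise_sd)
  if (!is.null(causal_index)) {
    stopifnot(causal_index >= 1, causal_index <= ncol(G$dosage))
    d <- G$dosage[, causal_index]
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    y <- y + beta * d
  }
  if (clamp) y <- pmin(pmax(y, 0), 100)
  y
}
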