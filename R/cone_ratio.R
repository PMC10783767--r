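#' Corrected %L from an FP-ERG signal fraction
#'
#' The flicker-photometric ERG pools signal from L and M cones, but each M
#' cone contributes `m_weight` (default 1.5) times as much signal as each L
#' cone.  With `S_L = n_L` and `S_M = w * n_M`, the observed L signal
#' fraction is `s = n_L / (n_L + w * n_M)`; solving for the cone-count
#' fraction gives the closed form
#' \deqn{\%L = 100 \cdot \frac{w s}{1 + (w - 1) s}.}
#' The map is strictly increasing in `s`, fixes the endpoints 0 and 100, and
#' reduces to `100 * s` when `w = 1`.
#'
#' @param s L-cone share of the summed FP-ERG signal, in \[0, 1\] (vector).
#' @param m_weight Per-cone M:L signal weight `w` (> 0, default 1.5).
#' @return Corrected %L in \[0, 100\].
#' @examples
#' corrected_percent_L(0.5)        # 60: equal signal implies 60% L cones
#' corrected_percent_L(0.5, m_weight = 1)  # 50: no correction
#' @export
corrected_percent_L <- function(s, m_weight = 1.5) {
  if (length(m_weight) != 1L || is.na(m_weight) || m_weight <= 0)
    stop("m_weight must be a single positive number", call. = FALSE)
  if (any(is.na(s)) || any(s < 0 | s > 1))
    stop("signal fractions must lie in [0, 1]", call. = FALSE)
  100 * m_weight * s / (1 + (m_weight - 1) * s)
}

#' @rdname corrected_percent_L
#' @param percent_L Corrected %L values in \[0, 100\].
#' @return `signal_fraction_from_percent_L` inverts the correction, returning
#'   the signal fraction `s`.
#' @export
signal_fraction_from_percent_L <- function(percent_L, m_weight = 1.5) {
  if (any(is.na(percent_L)) || any(percent_L < 0 | percent_L > 100))
    stop("percent_L must lie in [0, 100]", call. = FALSE)
  p <- percent_L / 100
  p / (m_weight - (m_weight - 1) * p)
}

#' Clamp over-range %L values
#'
#' FP-ERG %L estimates are nonlinear near saturation, and raw study values
#' can exceed 100%.  Values above 100 are clamped to 100 with a warning;
#' values below 0 are an error (they indicate a unit problem, not
#' saturation).
#'
#' @param percent_L Numeric vector.
#' @return The clamped vector.
#' @export
clamp_percent_L <- function(percent_L) {
  if (any(percent_L < 0, na.rm = TRUE))
    stop("negative %L values are not interpretable", call. = FALSE)
  over <- which(percent_L > 100)
  if (length(over)) {
    warning(length(over), " %L value(s) exceeded 100 and were clamped to 100",
            call. = FALSE)
    percent_L[over] <- 100
  }
  percent_L
}

#' Summarize cone counts as percentages
#'
#' Converts counts of M-only, L-only and co-expressing cones into percentages
#' of the M/L total, as used for regional and per-condition cone-ratio
#' summaries.
#'
#' @param n_M,n_L,n_coexpress Non-negative counts (co-expressing defaults
#'   to 0).
#' @param region Optional label (e.g. `"center"`, `"periphery"`, or a
#'   culture condition).
#' @return A one-row data frame: `region`, `n_M`, `n_L`, `n_coexpress`,
#'   `pct_M`, `pct_L`, `pct_co` (percentages summing to 100).
#' @examples
#' summarize_region_counts(13, 87)  # 13% M, 87% L
#' @export
summarize_region_counts <- function(n_M, n_L, n_coexpress = 0, region = NA) {
  if (any(c(n_M, n_L, n_coexpress) < 0))
    stop("counts must be non-negative", call. = FALSE)
  total <- n_M + n_L + n_coexpress
  if (total == 0) stop("all counts are zero", call. = FALSE)
  data.frame(region = region, n_M = n_M, n_L = n_L, n_coexpress = n_coexpress,
             pct_M = 100 * n_M / total, pct_L = 100 * n_L / total,
             pct_co = 100 * n_coexpress / total, stringsAsFactors = FALSE)
}

#' Genotype frequencies per %L decile
#'
#' Bins subjects into 10 equal-width %L bins on \[0, 100\] (matching the
#' decile axis used for cohort summaries; equal-width, not equal-count) and
#' tabulates genotype frequencies per bin.
#'
#' @param measurements A data frame with columns `percent_L` and `genotype`
#'   (subjects with missing genotype are dropped).
#' @param n_bins Number of equal-width bins (default 10).
#' @return A data frame: `bin`, `bin_low`, `bin_high`, `n`, then one
#'   frequency column per genotype level; frequencies sum to 1 in every
#'   nonempty bin.
#' @export
genotype_by_decile <- function(measurements, n_bins = 10) {
  stopifnot(is.data.frame(measurements),
            all(c("percent_L", "genotype") %in% names(measurements)))
  m <- measurements[!is.na(measurements$genotype), ]
  if (nrow(m) == 0L) stop("no genotyped subjects", call. = FALSE)
  breaks <- seq(0, 100, length.out = n_bins + 1)
  bin <- cut(m$percent_L, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  geno <- sort(unique(as.character(m$genotype)))
  tab <- table(factor(bin, levels = seq_len(n_bins)),
               factor(as.character(m$genotype), levels = geno))
  n <- rowSums(tab)
  freq <- sweep(tab, 1, pmax(n, 1), "/")
  out <- data.frame(bin = seq_len(n_bins),
                    bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
                    n = as.integer(n))
  for (g in geno) out[[g]] <- as.numeric(freq[, g])
  out
}

#' Read a phenotype table
#'
#' CSV with columns `subject_id`, and either `signal_fraction_L` (converted
#' via [corrected_percent_L()]) or `percent_L` directly; optional `genotype`.
#' %L values above 100 are clamped per [clamp_percent_L()].
#'
#' @param path CSV path.
#' @param m_weight Passed to [corrected_percent_L()] when converting signal
#'   fractions.
#' @return A data frame `subject_id`, `percent_L`, `genotype`.
#' @export
read_phenotypes <- function(path, m_weight = 1.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("phenotype table needs a subject_id column", call. = FALSE)
  if ("percent_L" %in% names(df)) {
    pl <- clamp_percent_L(df$percent_L)
  } else if ("signal_fraction_L" %in% names(df)) {
    pl <- corrected_percent_L(df$signal_fraction_L, m_weight)
  } else {
    stop("phenotype table needs percent_L or signal_fraction_L", call. = FALSE)
  }
  data.frame(subject_id = df$subject_id, percent_L = pl,
             genotype = if ("genotype" %in% names(df)) df$genotype else NA,
             stringsAsFactors = FALSE)
}
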