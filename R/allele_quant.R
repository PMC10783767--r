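#' Aligned-read tables
#'
#' Aligned reads are carried as a plain data frame with columns `read_id`,
#' `start` (1-based leftmost reference position), `seq`, `qual` (phred+33
#' string; optional, defaults to uniformly high quality), and optionally
#' `ref` (reference name) and `cigar` (when absent, reads are taken as
#' all-match, the form the bundled simulator emits).  `read_alignments_tsv`
#' and `write_alignments_tsv` round-trip this table; `read_alignments_bam`
#' imports the same columns from a BAM file via \pkg{Rsamtools}.
#'
#' @param path File path.
#' @return A reads data frame.
#' @export
read_alignments_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(seq = "character"))
  validate_reads(df)
}

#' @rdname read_alignments_tsv
#' @param reads A reads data frame.
#' @export
write_alignments_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_alignments_tsv
#' @export
read_alignments_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_alignments_bam requires the Rsamtools package", call. = FALSE)
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "seq", "qual", "cigar")))[[1]]
  keep <- !is.na(b$pos)
  validate_reads(data.frame(
    read_id = b$qname[keep], ref = as.character(b$rname)[keep],
    start = b$pos[keep], seq = as.character(b$seq)[keep],
    qual = as.character(b$qual)[keep], cigar = b$cigar[keep],
    stringsAsFactors = FALSE))
}

validate_reads <- function(reads) {
  req <- c("read_id", "start", "seq")
  missing <- setdiff(req, names(reads))
  if (length(missing))
    stop("reads table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(reads$start < 1L)) stop("read start positions must be >= 1", call. = FALSE)
  reads
}

phred_from_string <- function(q) as.integer(charToRaw(paste(q, collapse = ""))) - 33L

# reference position -> read offset for one CIGAR string; NA where the read
# has no base at that position (deletion / skip), offsets honor insertions
cigar_read_offset <- function(cigar, start, ref_pos) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("\\d+", "", ops)
  rpos <- as.integer(start)  # next reference position
  qoff <- 0L                 # read bases consumed
  ref_pos <- as.integer(ref_pos)
  out <- rep(NA_integer_, length(ref_pos))
  for (k in seq_along(op)) {
    if (op[k] %in% c("M", "=", "X")) {
      hit <- ref_pos >= rpos & ref_pos < rpos + n[k]
      out[hit] <- qoff + (ref_pos[hit] - rpos) + 1L
      rpos <- rpos + n[k]; qoff <- qoff + n[k]
    } else if (op[k] %in% c("D", "N")) {
      rpos <- rpos + n[k]
    } else if (op[k] %in% c("I", "S")) {
      qoff <- qoff + n[k]
    } # H, P consume nothing
  }
  out
}

#' Pileup of read bases at diagnostic sites
#'
#' Counts, for every diagnostic site, the read bases aligned over it.  A read
#' contributes at most one base per site; deleted positions contribute
#' nothing; bases below the quality floor are excluded from both the counts
#' and the depth.  Reads and site positions must share a reference frame
#' (choose it with `frame`): transcript-frame alignments against the site
#' table's `pos_a` or `pos_b` column.
#'
#' @param reads A reads data frame (see [read_alignments_tsv()]).
#' @param sites A `diagnostic_sites` data frame.
#' @param frame `"a"` or `"b"`: which paralog's transcript coordinates the
#'   reads are aligned to.
#' @param min_base_quality Phred floor; bases below it are dropped.  The
#'   default 13 corresponds to ~5% base-call error.
#' @param ref_length Optional reference length; site positions beyond it are
#'   an error.
#' @return A data frame of class `site_base_counts`: one row per site with
#'   `pos`, per-base counts `n_A`, `n_C`, `n_G`, `n_T`, `n_N`, and `depth`
#'   (= their sum).
#' @export
pileup_at_sites <- function(reads, sites, frame = c("a", "b"),
                            min_base_quality = 13, ref_length = NULL) {
  frame <- match.arg(frame)
  validate_reads(reads)
  stopifnot(inherits(sites, "diagnostic_sites"))
  pos <- sites[[paste0("pos_", frame)]]
  if (!is.null(ref_length) && any(pos > ref_length))
    stop("site position beyond reference length", call. = FALSE)
  has_qual <- !is.null(reads$qual)
  simple <- is.null(reads$cigar) || all(grepl("^\\d+M$", reads$cigar))
  rlen <- nchar(reads$seq)
  counts <- matrix(0L, nrow = length(pos), ncol = 5L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  for (i in seq_along(pos)) {
    p <- pos[i]
    span <- reads$start <= p & reads$start + rlen - 1L >= p
    idx <- which(span)
    if (!length(idx)) next
    if (simple) {
      off <- p - reads$start[idx] + 1L
    } else {
      off <- vapply(idx, function(r)
        cigar_read_offset(reads$cigar[r], reads$start[r], p), integer(1))
      keep <- !is.na(off)
      idx <- idx[keep]; off <- off[keep]
      if (!length(idx)) next
    }
    base <- toupper(substr(reads$seq[idx], off, off))
    if (has_qual) {
      q <- phred_from_string(substr(reads$qual[idx], off, off))
      ok <- q >= min_base_quality
      base <- base[ok]
    }
    base <- base[base %in% colnames(counts)]
    if (length(base)) {
      tab <- table(factor(base, levels = colnames(counts)))
      counts[i, ] <- counts[i, ] + as.integer(tab)
    }
  }
  out <- data.frame(pos = pos, stringsAsFactors = FALSE)
  out$n_A <- counts[, "A"]; out$n_C <- counts[, "C"]
  out$n_G <- counts[, "G"]; out$n_T <- counts[, "T"]
  out$n_N <- counts[, "N"]
  out$depth <- as.integer(rowSums(counts))
  class(out) <- c("site_base_counts", "data.frame")
  out
}

#' Assign pileup bases to paralog alleles
#'
#' Splits each site's pileup into `count_a` (bases matching the site's
#' paralog-a allele), `count_b`, and `count_other` (anything else, including
#' N), so that `count_a + count_b + count_other = depth`.
#'
#' @param counts A `site_base_counts` from [pileup_at_sites()].
#' @param sites The matching `diagnostic_sites` data frame (same row order).
#' @return A data frame of class `site_pileup`: per site `pos_a`, `pos_b`,
#'   `base_a`, `base_b`, `count_a`, `count_b`, `count_other`, `depth`.
#' @export
assign_site_counts <- function(counts, sites) {
  stopifnot(inherits(counts, "site_base_counts"),
            inherits(sites, "diagnostic_sites"),
            nrow(counts) == nrow(sites))
  base_mat <- as.matrix(counts[, c("n_A", "n_C", "n_G", "n_T", "n_N")])
  base_col <- function(b) {
    as.integer(base_mat[cbind(seq_len(nrow(counts)),
                              match(b, c("A", "C", "G", "T", "N")))])
  }
  count_a <- base_col(sites$base_a)
  count_b <- base_col(sites$base_b)
  out <- data.frame(pos_a = sites$pos_a, pos_b = sites$pos_b,
                    base_a = sites$base_a, base_b = sites$base_b,
                    count_a = count_a, count_b = count_b,
                    count_other = counts$depth - count_a - count_b,
                    depth = counts$depth, stringsAsFactors = FALSE)
  class(out) <- c("site_pileup", "data.frame")
  out
}

#' Normalized pileup counts
#'
#' The per-site expression statistic: each allele count divided by the total
#' number of aligned reads in the sample, scaled to counts per million by
#' default.  Whether the denominator is total aligned or total sequenced
#' reads is the caller's choice -- pass whichever count is appropriate.
#'
#' @param result A `site_pileup` from [assign_site_counts()].
#' @param total_reads Total read count of the sample (> 0).
#' @param scale Scale factor (default 1e6: counts per million).
#' @return The input with `normalized_a` and `normalized_b` columns added.
#' @export
normalize_counts <- function(result, total_reads, scale = 1e6) {
  stopifnot(inherits(result, "site_pileup"))
  if (length(total_reads) != 1L || is.na(total_reads) || total_reads <= 0)
    stop("total_reads must be a single positive number", call. = FALSE)
  result$normalized_a <- scale * result$count_a / total_reads
  result$normalized_b <- scale * result$count_b / total_reads
  result
}

wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Pooled paralog mixture estimate
#'
#' Pools allele counts across diagnostic sites and estimates the fraction of
#' expression attributable to paralog a, with a 95% Wilson score interval on
#' the pooled informative count.  The interval treats pooled allele
#' observations as independent, which holds when diagnostic sites are farther
#' apart than the read length.
#'
#' @param result A `site_pileup`.
#' @param conf Confidence level (default 0.95).
#' @return A list of class `mixture_estimate`: `fraction_a`, `ci_low`,
#'   `ci_high`, `n_informative`.
#' @export
estimate_mixture <- function(result, conf = 0.95) {
  stopifnot(inherits(result, "site_pileup"))
  xa <- sum(result$count_a)
  n <- xa + sum(result$count_b)
  if (n == 0L)
    stop("no informative allele counts at any site", call. = FALSE)
  ci <- wilson_interval(xa, n, conf)
  structure(list(fraction_a = xa / n, ci_low = unname(ci["low"]),
                 ci_high = unname(ci["high"]), n_informative = n),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf("paralog-a fraction %.4f (95%% CI %.4f-%.4f, n = %d informative bases)\n",
              x$fraction_a, x$ci_low, x$ci_high, x$n_informative))
  invisible(x)
}

#' Read-level paralog classification
#'
#' Optional extension to the per-site pileup view: classifies each read by
#' the diagnostic alleles it spans -- `"a"` or `"b"` when all spanned sites
#' agree, `"conflicting"` when they disagree, `"ambiguous"` when the read
#' covers no informative base.
#'
#' @inheritParams pileup_at_sites
#' @return A data frame `read_id`, `n_a`, `n_b`, `call`.
#' @export
classify_reads <- function(reads, sites, frame = c("a", "b"),
                           min_base_quality = 13) {
  frame <- match.arg(frame)
  validate_reads(reads)
  pos <- sites[[paste0("pos_", frame)]]
  has_qual <- !is.null(reads$qual)
  rlen <- nchar(reads$seq)
  n_a <- n_b <- integer(nrow(reads))
  for (i in seq_along(pos)) {
    p <- pos[i]
    idx <- which(reads$start <= p & reads$start + rlen - 1L >= p)
    if (!length(idx)) next
    off <- p - reads$start[idx] + 1L
    base <- toupper(substr(reads$seq[idx], off, off))
    if (has_qual) {
      q <- phred_from_string(substr(reads$qual[idx], off, off))
      base[q < min_base_quality] <- "."
    }
    n_a[idx] <- n_a[idx] + (base == sites$base_a[i])
    n_b[idx] <- n_b[idx] + (base == sites$base_b[i])
  }
  call <- ifelse(n_a > 0 & n_b > 0, "conflicting",
                 ifelse(n_a > 0, "a", ifelse(n_b > 0, "b", "ambiguous")))
  data.frame(read_id = reads$read_id, n_a = n_a, n_b = n_b, call = call,
             stringsAsFactors = FALSE)
}
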