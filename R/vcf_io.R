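#' Read a Freebayes-dialect VCF
#'
#' Imports a VCF (4.2) via \pkg{vcfR}, extracting the fixed fields, the INFO
#' keys the variant filter needs (AO, SAF, SAR, RPR, RPL, and DP/RO when
#' present), and the genotype calls as a dosage matrix.  Single-allele GT
#' strings (`0` / `1` / `.`) are read as haploid calls; `a/b` or `a|b` as
#' diploid.
#'
#' @param path VCF path (plain or bgzipped).
#' @return A list with `records` (data frame for [filter_variant_calls()])
#'   and `genotypes` (a [genotype_matrix()]).
#' @export
read_freebayes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_num <- function(key) {
    x <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
    if (length(x) == 0L) rep(NA_real_, nrow(fix)) else x
  }
  records <- data.frame(
    chrom = fix$CHROM, pos = as.numeric(fix$POS), ref = fix$REF,
    alt = fix$ALT, qual = suppressWarnings(as.numeric(fix$QUAL)),
    AO = info_num("AO"), SAF = info_num("SAF"), SAR = info_num("SAR"),
    RPR = info_num("RPR"), RPL = info_num("RPL"),
    DP = info_num("DP"), RO = info_num("RO"),
    stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("[|/]", "", gt)
  ploidy <- if (any(grepl("[|/]", gt[!is.na(gt)]))) 2L else 1L
  dosage <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                   dimnames = list(colnames(gt), rownames(gt)))
  for (j in seq_len(nrow(gt))) {
    a <- alleles[j, ]
    d <- vapply(strsplit(a, ""), function(s)
      if (length(s) == 0L || anyNA(s) || any(s == ".")) NA_real_
      else sum(s == "1"), numeric(1))
    dosage[, j] <- d
  }
  list(records = records,
       genotypes = genotype_matrix(dosage, records$chrom, records$pos,
                                   ploidy = ploidy))
}

#' Write a cohort as a Freebayes-dialect VCF
#'
#' Serializes a [genotype_matrix()] (plus optional per-variant QC fields) to
#' VCF 4.2 through \pkg{vcfR}.  The output is bgzip-compressed
#' (`vcfR::write.vcf`), so use a `.vcf.gz` path.
#'
#' @param G A [genotype_matrix()].
#' @param path Output path (`.vcf.gz`).
#' @param records Optional data frame supplying `ref`, `alt`, `qual`, `AO`,
#'   `SAF`, `SAR`, `RPR`, `RPL` per variant; sensible placeholders are
#'   written otherwise.
#' @export
write_cohort_vcf <- function(G, path, records = NULL) {
  m <- ncol(G$dosage)
  n <- nrow(G$dosage)
  if (is.null(records)) {
    records <- data.frame(ref = rep("A", m), alt = rep("G", m),
                          qual = rep(1000, m), AO = rep(10, m),
                          SAF = rep(5, m), SAR = rep(5, m),
                          RPR = rep(5, m), RPL = rep(5, m),
                          stringsAsFactors = FALSE)
  }
  info <- sprintf("AO=%g;SAF=%g;SAR=%g;RPR=%g;RPL=%g",
                  records$AO, records$SAF, records$SAR,
                  records$RPR, records$RPL)
  fix <- cbind(CHROM = G$chrom, POS = as.character(G$pos), ID = G$id,
               REF = records$ref, ALT = records$alt,
               QUAL = as.character(records$qual), FILTER = ".", INFO = info)
  samples <- rownames(G$dosage)
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(n))
  gt_chr <- matrix(".", nrow = m, ncol = n, dimnames = list(NULL, samples))
  for (i in seq_len(n)) {
    d <- G$dosage[i, ]
    gt_chr[, i] <- if (G$ploidy == 1L) ifelse(is.na(d), ".", as.character(d))
    else ifelse(is.na(d), "./.",
                c("0/0", "0/1", "1/1")[d + 1])
  }
  gt <- cbind(FORMAT = "GT", gt_chr)
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observations\">",
            "##INFO=<ID=SAF,Number=A,Type=Integer,Description=\"Alt observations on the forward strand\">",
            "##INFO=<ID=SAR,Number=A,Type=Integer,Description=\"Alt observations on the reverse strand\">",
            "##INFO=<ID=RPR,Number=A,Type=Integer,Description=\"Alt reads placed right of the allele\">",
            "##INFO=<ID=RPL,Number=A,Type=Integer,Description=\"Alt reads placed left of the allele\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cls <- methods::getClassDef("vcfR", package = "vcfR")
  obj <- methods::new(cls, meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}
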