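#' opsinquant: paralog-specific opsin expression and cone-ratio genetics
#'
#' The X-linked long- and middle-wavelength opsin genes (OPN1LW, OPN1MW) are
#' so similar (~96% at the protein level, ~98% at the mRNA level) that
#' standard probes and read counting cannot tell them apart.  opsinquant works
#' from the small set of nucleotide positions at which the two transcripts
#' differ: it finds those diagnostic sites, designs discriminating probe
#' windows around them, quantifies paralog-specific expression by counting
#' read bases at the sites, converts flicker-photometric ERG signal fractions
#' into corrected %L cone ratios, and scans targeted-sequencing cohorts for
#' variants associated with the cone ratio.  Simulators for paralog pairs,
#' mixed-origin reads and structured haploid cohorts make every stage
#' testable without external data.
#'
#' @keywords internal
"_PACKAGE"

GAP_CHAR <- "-"
DNA_CHARS <- c("A", "C", "G", "T", "N")
AA_CHARS <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
              "S","T","W","Y","V","X","*")

check_sequence <- function(x, alphabet = c("dna", "protein"), arg = "sequence") {
  alphabet <- match.arg(alphabet)
  if (length(x) != 1L || !is.character(x) || is.na(x) || nchar(x) == 0L)
    stop(arg, " must be a single non-empty character string", call. = FALSE)
  x <- toupper(x)
  ok <- if (alphabet == "dna") DNA_CHARS else AA_CHARS
  bad <- setdiff(unique(strsplit(x, "")[[1]]), ok)
  if (length(bad))
    stop(arg, " contains characters outside the ", alphabet, " alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  x
}

#' Globally align two paralogous sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed with
#' \code{Biostrings::pairwiseAlignment}.  The default scoring (match +1,
#' mismatch -1, gap open -5, gap extend -1) is deliberately mild: the intended
#' inputs are near-identical paralogs, for which the alignment is insensitive
#' to the exact scheme.
#'
#' @param seq_a,seq_b Character strings (DNA or protein, both the same
#'   alphabet).
#' @param alphabet `"dna"` or `"protein"`.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.  Penalties
#'   are given as the (negative) score contribution, as conventional.
#' @return An object of class `paralog_alignment`: a list with aligned
#'   character vectors `a` and `b` (one element per column, gaps as `"-"`),
#'   and integer coordinate maps `map_a`, `map_b` giving the 1-based ungapped
#'   position of each column in each input (`NA` at gaps).
#' @examples
#' aln <- align_paralogs("ACGTACGTAC", "ACGAACGTAC")
#' percent_identity(aln)
#' @export
align_paralogs <- function(seq_a, seq_b, alphabet = c("dna", "protein"),
                           match = 1, mismatch = -1,
                           gap_open = -5, gap_extend = -1) {
  alphabet <- match.arg(alphabet)
  seq_a <- check_sequence(seq_a, alphabet, "seq_a")
  seq_b <- check_sequence(seq_b, alphabet, "seq_b")
  letters <- if (alphabet == "dna") DNA_CHARS else AA_CHARS
  submat <- matrix(mismatch, length(letters), length(letters),
                   dimnames = list(letters, letters))
  diag(submat) <- match
  pa <- Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b, type = "global",
    substitutionMatrix = submat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  new_paralog_alignment(a, b, alphabet)
}

new_paralog_alignment <- function(a, b, alphabet) {
  stopifnot(length(a) == length(b))
  map_a <- ifelse(a == GAP_CHAR, NA_integer_, cumsum(a != GAP_CHAR))
  map_b <- ifelse(b == GAP_CHAR, NA_integer_, cumsum(b != GAP_CHAR))
  structure(list(a = a, b = b, map_a = map_a, map_b = map_b,
                 alphabet = alphabet),
            class = "paralog_alignment")
}

#' @export
print.paralog_alignment <- function(x, ...) {
  n <- length(x$a)
  mism <- sum(x$a != x$b & x$a != GAP_CHAR & x$b != GAP_CHAR)
  gaps <- sum(x$a == GAP_CHAR | x$b == GAP_CHAR)
  cat(sprintf("paralog_alignment: %d columns (%s), %d substitution(s), %d gap column(s)\n",
              n, x$alphabet, mism, gaps))
  invisible(x)
}

degap <- function(track) paste(track[track != GAP_CHAR], collapse = "")

#' Percent identity of a pairwise alignment
#'
#' By default the denominator is the number of columns where both tracks are
#' non-gap (gap-excluded identity), the convention under which the opsin
#' mRNAs are quoted as ~98% and the proteins as ~96% identical.  Set
#' `denominator = "all"` to divide by every alignment column instead.
#'
#' @param aln A [align_paralogs()] result.
#' @param denominator `"aligned"` (both non-gap; default) or `"all"`.
#' @return Percentage in \[0, 100\].
#' @export
percent_identity <- function(aln, denominator = c("aligned", "all")) {
  stopifnot(inherits(aln, "paralog_alignment"))
  denominator <- match.arg(denominator)
  both <- aln$a != GAP_CHAR & aln$b != GAP_CHAR
  n <- if (denominator == "aligned") sum(both) else length(aln$a)
  if (n == 0L) stop("alignment has no aligned columns", call. = FALSE)
  100 * sum(both & aln$a == aln$b) / n
}

site_table_columns <- c("exon", "base_a", "base_b", "pos_a", "pos_b",
                        "exon_pos", "genome_pos_a", "genome_pos_b")

new_site_table <- function(df) {
  for (col in setdiff(site_table_columns, names(df))) {
    df[[col]] <- rep(if (col == "exon") NA_character_ else NA_integer_,
                     nrow(df))
  }
  for (col in c("pos_a", "pos_b", "exon_pos"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("genome_pos_a", "genome_pos_b"))
    df[[col]] <- as.numeric(df[[col]])
  df <- df[, site_table_columns]
  class(df) <- c("diagnostic_sites", "data.frame")
  validate_site_table(df)
  df
}

validate_site_table <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$base_a == df$base_b))
    stop("diagnostic sites must differ between paralogs", call. = FALSE)
  if (is.unsorted(df$pos_a, strictly = TRUE) ||
      is.unsorted(df$pos_b, strictly = TRUE))
    stop("site positions must be strictly increasing in both paralogs",
         call. = FALSE)
  invisible(df)
}

#' Extract diagnostic sites from a nucleotide alignment
#'
#' A diagnostic site is an alignment column where both paralogs carry a
#' (non-gap, non-N) base and the bases differ.  Gap columns never form sites,
#' and ambiguity codes are ignored: a probe or pileup can only discriminate
#' on a definite substitution.
#'
#' @param aln A nucleotide [align_paralogs()] result.
#' @return A `diagnostic_sites` data frame with one row per substitution
#'   column, sorted by `pos_a`, columns `exon`, `base_a`, `base_b`, `pos_a`,
#'   `pos_b`, `exon_pos`, `genome_pos_a`, `genome_pos_b` (annotation columns
#'   `NA` until filled by [annotate_sites()]).
#' @export
find_diagnostic_sites <- function(aln) {
  stopifnot(inherits(aln, "paralog_alignment"))
  if (aln$alphabet != "dna")
    stop("diagnostic sites are defined for nucleotide alignments only",
         call. = FALSE)
  keep <- aln$a != GAP_CHAR & aln$b != GAP_CHAR & aln$a != aln$b &
    aln$a != "N" & aln$b != "N"
  new_site_table(data.frame(
    base_a = aln$a[keep], base_b = aln$b[keep],
    pos_a = aln$map_a[keep], pos_b = aln$map_b[keep],
    stringsAsFactors = FALSE))
}

#' Read / write a diagnostic-site table
#'
#' Plain TSV with header columns `exon`, `base_a`, `base_b`, `pos_a`,
#' `pos_b`, `exon_pos`, `genome_pos_a`, `genome_pos_b`; one row per
#' diagnostic site, sorted by transcript position.
#'
#' @param path File path.
#' @return `read_site_table` returns a `diagnostic_sites` data frame.
#' @export
read_site_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(exon = "character"))
  missing <- setdiff(site_table_columns, names(df))
  if (length(missing))
    stop("site table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  new_site_table(df)
}

#' @rdname read_site_table
#' @param sites A `diagnostic_sites` data frame.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(as.data.frame(sites)[, site_table_columns], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The bundled OPN1LW/OPN1MW diagnostic-site table
#'
#' The 20 nucleotide positions distinguishing the human L-opsin (OPN1LW,
#' NM_020061.5; paralog "a") and M-opsin (OPN1MW, NM_000513.2; paralog "b")
#' transcripts, with exon labels, within-exon positions and GRCh38 chrX
#' coordinates.  These positions drive both probe design and the
#' diagnostic-site pileup quantification.
#'
#' @return A `diagnostic_sites` data frame with 20 rows.
#' @examples
#' sites <- opsin_sites()
#' nrow(sites)
#' @export
opsin_sites <- function() {
  read_site_table(system.file("extdata", "opsin_diagnostic_sites.tsv",
                              package = "opsinquant", mustWork = TRUE))
}

#' Annotate diagnostic sites with exon and genomic coordinates
#'
#' @param sites A `diagnostic_sites` data frame.
#' @param exon_map_a,exon_map_b [exon_map()] for each paralog (either may be
#'   `NULL` to leave that side unannotated).
#' @return The site table with `exon`, `exon_pos`, `genome_pos_a`,
#'   `genome_pos_b` filled in where a map covers the position.  `exon` and
#'   `exon_pos` are taken from paralog a's map when available, otherwise b's.
#' @export
annotate_sites <- function(sites, exon_map_a = NULL, exon_map_b = NULL) {
  stopifnot(inherits(sites, "diagnostic_sites"))
  ann <- function(map, pos) {
    ex <- locate_exon(pos, map)
    list(exon = map$exon[ex],
         exon_pos = pos - map$tstart[ex] + 1L,
         gpos = vapply(pos, map_transcript_coordinates, numeric(1),
                       exon_map = map, direction = "to_genome"))
  }
  if (!is.null(exon_map_a)) {
    a <- ann(exon_map_a, sites$pos_a)
    sites$exon <- a$exon; sites$exon_pos <- a$exon_pos
    sites$genome_pos_a <- a$gpos
  }
  if (!is.null(exon_map_b)) {
    b <- ann(exon_map_b, sites$pos_b)
    if (is.null(exon_map_a)) { sites$exon <- b$exon; sites$exon_pos <- b$exon_pos }
    sites$genome_pos_b <- b$gpos
  }
  sites
}

#' Build an exon map
#'
#' An exon map relates a transcript's 1-based coordinate system to genomic
#' coordinates, one affine offset per exon.  All intervals are 1-based and
#' fully closed.
#'
#' @param exon Character exon labels.
#' @param tstart,tend Transcript interval per exon (contiguous,
#'   non-overlapping, increasing).
#' @param gstart,gend Genomic interval per exon; must have the same length
#'   as the transcript interval.
#' @param strand `"+"` or `"-"` (one value for the whole transcript).
#' @return An `exon_map` data frame.
#' @export
exon_map <- function(exon, tstart, tend, gstart, gend, strand = "+") {
  strand <- match.arg(strand, c("+", "-"))
  df <- data.frame(exon = as.character(exon), tstart = as.integer(tstart),
                   tend = as.integer(tend), gstart = as.numeric(gstart),
                   gend = as.numeric(gend), stringsAsFactors = FALSE)
  df <- df[order(df$tstart), ]
  if (any(df$tend - df$tstart != df$gend - df$gstart))
    stop("transcript and genomic interval lengths differ", call. = FALSE)
  if (any(df$tstart > df$tend))
    stop("invalid transcript intervals", call. = FALSE)
  if (nrow(df) > 1L && any(utils::head(df$tend, -1) >= df$tstart[-1]))
    stop("transcript intervals overlap", call. = FALSE)
  attr(df, "strand") <- strand
  class(df) <- c("exon_map", "data.frame")
  df
}

locate_exon <- function(pos, map) {
  idx <- vapply(pos, function(p) {
    hit <- which(map$tstart <= p & p <= map$tend)
    if (length(hit) != 1L) NA_integer_ else hit
  }, integer(1))
  if (anyNA(idx))
    stop("position(s) outside all mapped exons: ",
         paste(pos[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' Map a position between transcript, exon, and genome frames
#'
#' Each exon contributes a constant offset: on the plus strand
#' `gpos = gstart + (pos - tstart)`; on the minus strand the interval is
#' mirrored, `gpos = gend - (pos - tstart)`.
#'
#' @param pos A single 1-based position (transcript frame for `to_genome` /
#'   `to_exon`, genomic frame for `from_genome`).
#' @param exon_map An [exon_map()].
#' @param direction `"to_genome"`, `"to_exon"` or `"from_genome"`.
#' @return The mapped position (for `"to_exon"`, a list with `exon` and
#'   `exon_pos`).
#' @examples
#' m <- opsin_exon_map("b")  # M-opsin, fitted to the bundled site table
#' map_transcript_coordinates(902, m, "to_genome")
#' @export
map_transcript_coordinates <- function(pos, exon_map,
                                       direction = c("to_genome", "to_exon",
                                                     "from_genome")) {
  direction <- match.arg(direction)
  stopifnot(inherits(exon_map, "exon_map"), length(pos) == 1L, pos > 0)
  strand <- attr(exon_map, "strand")
  if (direction == "from_genome") {
    hit <- which(exon_map$gstart <= pos & pos <= exon_map$gend)
    if (length(hit) != 1L)
      stop("genomic position outside all mapped exons: ", pos, call. = FALSE)
    return(if (strand == "+")
      exon_map$tstart[hit] + (pos - exon_map$gstart[hit])
      else exon_map$tstart[hit] + (exon_map$gend[hit] - pos))
  }
  ex <- locate_exon(pos, exon_map)
  if (direction == "to_exon")
    return(list(exon = exon_map$exon[ex],
                exon_pos = pos - exon_map$tstart[ex] + 1L))
  if (strand == "+")
    exon_map$gstart[ex] + (pos - exon_map$tstart[ex])
  else
    exon_map$gend[ex] - (pos - exon_map$tstart[ex])
}

#' Fit an exon map to an annotated site table
#'
#' Estimates one transcript-to-genome offset per exon from the site rows
#' (majority offset), taking each exon's transcript interval as the span of
#' its sites.  Rows whose own offset disagrees with the exon majority are
#' flagged -- never silently corrected -- in the `"inconsistent_rows"`
#' attribute, with a warning.  The bundled L-opsin annotation carries such an
#' inconsistency: its exon-5 genomic offsets jump by 8 between transcript
#' positions 895 and 901.
#'
#' @param sites An annotated `diagnostic_sites` data frame.
#' @param paralog `"a"` or `"b"`: which paralog's positions to fit.
#' @return An [exon_map()] with attribute `"inconsistent_rows"` (integer row
#'   indices of `sites` that disagree with their exon's majority offset).
#' @export
fit_exon_map <- function(sites, paralog = c("a", "b")) {
  paralog <- match.arg(paralog)
  stopifnot(inherits(sites, "diagnostic_sites"))
  pos <- sites[[paste0("pos_", paralog)]]
  gpos <- sites[[paste0("genome_pos_", paralog)]]
  if (anyNA(gpos) || anyNA(sites$exon))
    stop("sites must carry exon labels and genomic positions", call. = FALSE)
  offs <- gpos - pos
  exons <- unique(sites$exon)
  bad <- integer(0)
  rows <- lapply(exons, function(e) {
    in_e <- which(sites$exon == e)
    tab <- table(offs[in_e])
    maj <- as.numeric(names(tab)[which.max(tab)])
    bad <<- c(bad, in_e[offs[in_e] != maj])
    data.frame(exon = e, tstart = min(pos[in_e]), tend = max(pos[in_e]),
               gstart = maj + min(pos[in_e]), gend = maj + max(pos[in_e]),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  out <- exon_map(map$exon, map$tstart, map$tend, map$gstart, map$gend, "+")
  attr(out, "inconsistent_rows") <- sort(bad)
  if (length(bad))
    warning(sprintf(
      "%d site row(s) disagree with their exon's majority genomic offset (rows %s); flagged, not corrected",
      length(bad), paste(sort(bad), collapse = ", ")), call. = FALSE)
  out
}

#' Exon maps for the bundled opsin site table
#'
#' Convenience wrapper: [fit_exon_map()] applied to [opsin_sites()].  The
#' M-opsin map (`"b"`) has constant per-exon offsets and round-trips all 20
#' positions; the L-opsin map (`"a"`) triggers the inconsistency warning
#' described in [fit_exon_map()].
#'
#' @param paralog `"a"` (L-opsin, NM_020061.5) or `"b"` (M-opsin,
#'   NM_000513.2).
#' @return An [exon_map()].
#' @export
opsin_exon_map <- function(paralog = c("b", "a")) {
  fit_exon_map(opsin_sites(), match.arg(paralog))
}

#' Read / write FASTA sequences as named character vectors
#'
#' Thin wrappers over \code{Biostrings::readDNAStringSet} /
#' \code{writeXStringSet}.
#'
#' @param path FASTA file path.
#' @return `read_fasta` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
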