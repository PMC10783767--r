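one_read <- function(seq, start = 1L, qual = strrep("I", nchar(seq)),
                     cigar = NULL) {
  df <- data.frame(read_id = "r1", start = start, seq = seq, qual = qual,
                   stringsAsFactors = FALSE)
  if (!is.null(cigar)) df$cigar <- cigar
  df
}

test_that("pileup respects coverage, the quality floor, and deletions", {
  sites <- make_sites(5, 5, "A", "G")
  rd <- one_read("CCCCACCC")
  pc <- pileup_at_sites(rd, sites)
  expect_identical(pc$depth, 1L)
  expect_identical(pc$n_A, 1L)

  # same read, base below the phred floor: excluded from counts and depth
  lowq <- one_read("CCCCACCC", qual = paste0(strrep("I", 4), "+", strrep("I", 3)))
  expect_identical(pileup_at_sites(lowq, sites)$depth, 0L)
  expect_identical(pileup_at_sites(lowq, sites, min_base_quality = 5)$depth, 1L)

  # a deletion spanning the site contributes nothing
  del <- one_read("CCCCCC", cigar = "4M2D2M")    # covers ref 1-8, no base at 5-6
  expect_identical(pileup_at_sites(del, sites)$depth, 0L)
  # an insertion before the site shifts the read offset
  ins <- one_read("CCTTCCACC", cigar = "2M2I5M") # ref 5 is read base 7 ("A")
  pc_ins <- pileup_at_sites(ins, make_sites(5, 5, "A", "G"))
  expect_identical(pc_ins$n_A, 1L)

  expect_error(pileup_at_sites(rd, sites, ref_length = 3), "beyond")
})

test_that("per-site depth equals a brute-force read-by-site overlap count", {
  tr <- make_paralog_pair(400, 10, seed = 5)
  rd <- simulate_reads(tr, pi_a = 0.5, depth = 30, read_len = 50,
                       error_rate = 0.01, seed = 5)
  pc <- pileup_at_sites(rd, tr$sites)
  brute <- vapply(tr$sites$pos_a, function(p)
    sum(rd$start <= p & rd$start + nchar(rd$seq) - 1L >= p), integer(1))
  expect_equal(pc$depth, brute)
  expect_equal(pc$n_A + pc$n_C + pc$n_G + pc$n_T + pc$n_N, pc$depth)
})

test_that("allele assignment partitions the depth", {
  sites <- make_sites(c(10, 20), c(10, 20), c("A", "A"), c("G", "G"))
  counts <- make_base_counts(c(10, 20), A = c(10, 0), G = c(5, 0), C = c(0, 7))
  res <- assign_site_counts(counts, sites)
  expect_equal(res$count_a, c(10, 0))
  expect_equal(res$count_b, c(5, 0))
  expect_equal(res$count_other, c(0, 7))
  expect_equal(res$count_a + res$count_b + res$count_other, res$depth)
})

test_that("error-free single-source reads never carry the other allele", {
  tr <- make_paralog_pair(600, 12, seed = 9)
  rd <- simulate_reads(tr, pi_a = 1, depth = 40, read_len = 60,
                       error_rate = 0, seed = 9)
  res <- assign_site_counts(pileup_at_sites(rd, tr$sites), tr$sites)
  expect_true(all(res$count_b == 0))
  expect_true(all(res$count_other == 0))
  expect_gt(sum(res$count_a), 0)
})

test_that("normalization scales counts per total reads", {
  sites <- make_sites(10, 10, "A", "G")
  res <- assign_site_counts(make_base_counts(10, A = 50), sites)
  out <- normalize_counts(res, total_reads = 1e6)
  expect_equal(out$normalized_a, 50)
  expect_equal(out$normalized_b, 0)
  expect_equal(normalize_counts(res, 1e6, scale = 1)$normalized_a, 5e-5)
  expect_error(normalize_counts(res, 0), "positive")
})

test_that("normalized values are depth-invariant in expectation", {
  tr <- make_paralog_pair(800, 10, seed = 21)
  norm_mean <- function(depth) {
    vals <- vapply(1:20, function(s) {
      rd <- simulate_reads(tr, pi_a = 0.6, depth = depth, read_len = 60,
                           error_rate = 0.005, seed = 100 + s)
      res <- assign_site_counts(pileup_at_sites(rd, tr$sites), tr$sites)
      mean(normalize_counts(res, total_reads = nrow(rd))$normalized_a)
    }, numeric(1))
    mean(vals)
  }
  m1 <- norm_mean(30); m2 <- norm_mean(60)
  expect_lt(abs(m1 - m2) / m1, 0.1)
})

test_that("the Wilson interval matches an independent implementation", {
  for (x in c(1, 20, 75, 99)) {
    ours <- opsinquant:::wilson_interval(x, 100)
    ref <- prop.test(x, 100, correct = FALSE)$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("pooled mixture estimation recovers composition with a valid interval", {
  sites <- make_sites(c(10, 30), c(10, 30), c("A", "C"), c("G", "T"))
  res <- assign_site_counts(
    make_base_counts(c(10, 30), A = c(40, 0), G = c(20, 0),
                     C = c(0, 35), T = c(0, 5)), sites)
  est <- estimate_mixture(res)
  expect_equal(est$fraction_a, 0.75)
  expect_identical(est$n_informative, 100L)
  expect_true(est$ci_low <= est$fraction_a && est$fraction_a <= est$ci_high)

  pure <- assign_site_counts(make_base_counts(10, A = 12),
                             make_sites(10, 10, "A", "G"))
  expect_equal(estimate_mixture(pure)$fraction_a, 1.0)
  none <- assign_site_counts(make_base_counts(10, C = 5),
                             make_sites(10, 10, "A", "G"))
  expect_error(estimate_mixture(none), "informative")
})

test_that("sequencing errors land on non-allele bases at the expected rate", {
  eps <- 0.01
  tr <- make_paralog_pair(2000, 20, seed = 31)
  rd <- simulate_reads(tr, pi_a = 0.5, depth = 400, read_len = 75,
                       error_rate = eps, seed = 31)
  res <- assign_site_counts(pileup_at_sites(rd, tr$sites), tr$sites)
  frac_other <- sum(res$count_other) / sum(res$depth)
  expected <- 2 * eps / 3        # errors to the two non-allele bases
  se <- sqrt(expected * (1 - expected) / sum(res$depth))
  expect_lt(abs(frac_other - expected), 4 * se + 1e-4)
})

test_that("mixture recovery approaches the simulated proportion", {
  tr <- make_paralog_pair(3000, 20, seed = 41)
  rd <- simulate_reads(tr, pi_a = 0.87, depth = 300, read_len = 75,
                       error_rate = 0.005, seed = 41)
  est <- estimate_mixture(assign_site_counts(pileup_at_sites(rd, tr$sites),
                                             tr$sites))
  se <- sqrt(0.87 * 0.13 / est$n_informative)
  expect_lt(abs(est$fraction_a - 0.87), 3 * se + 0.01)
})

test_that("read-level classification separates sources when errors are absent", {
  tr <- make_paralog_pair(500, 10, seed = 51)
  rd <- simulate_reads(tr, pi_a = 0.5, depth = 20, read_len = 60,
                       error_rate = 0, seed = 51)
  cls <- classify_reads(rd, tr$sites)
  informative <- cls$call %in% c("a", "b")
  expect_true(all(cls$call[informative] == rd$source[informative]))
  expect_false(any(cls$call == "conflicting"))
})

test_that("reads tables round-trip through TSV", {
  tr <- make_paralog_pair(200, 5, seed = 61)
  rd <- simulate_reads(tr, 0.5, depth = 5, read_len = 40, seed = 61)
  path <- tempfile(fileext = ".tsv")
  write_alignments_tsv(rd, path)
  back <- read_alignments_tsv(path)
  expect_equal(back$seq, rd$seq)
  expect_equal(back$start, rd$start)
})
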