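make_planted_genome <- function(seed, len, left, right, gap) {
  # plant left site + gap + right site (right's plus-strand image) mid-genome
  set.seed(seed)
  g <- rand_genome(len)
  at <- len %/% 2
  insert <- paste0(left, paste(rep("A", gap), collapse = ""), rc_chr(right))
  substr(g, at + 1, at + nchar(insert)) <- insert
  list(genome = g, left_start0 = at,
       product = nchar(left) + gap + nchar(right))
}

test_that("a planted perfect pair is found with the exact product size", {
  set.seed(1)
  left <- rand_genome(15); right <- rand_genome(15)
  pg <- make_planted_genome(2, 20000, left, right, 50)  # product 80
  hits <- scan_paired_sites(c(chr1 = pg$genome), left, right, 8, 100)
  planted <- hits[hits$left_start == pg$left_start0, ]
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$product_size, 80L)
  expect_identical(planted$left_perfect_match, 15L)
  expect_identical(planted$right_perfect_match, 15L)
})

test_that("the maximum product size is a hard boundary", {
  set.seed(3)
  left <- rand_genome(15); right <- rand_genome(15)
  pg <- make_planted_genome(4, 20000, left, right, 71)  # product 101
  hits <- scan_paired_sites(c(chr1 = pg$genome), left, right,
                            min_perfect_match = 15, max_product = 100)
  expect_identical(nrow(hits), 0L)
  hits2 <- scan_paired_sites(c(chr1 = pg$genome), left, right, 15, 101)
  expect_identical(nrow(hits2), 1L)
  expect_identical(hits2$product_size, 101L)
})

test_that("arms absent from a random genome return no hits at full stringency", {
  g <- rand_genome(50000, seed = 5)
  set.seed(99)
  repeat {
    left <- rand_genome(15); right <- rand_genome(15)
    if (!grepl(left, g, fixed = TRUE) &&
        !grepl(rc_chr(right), g, fixed = TRUE)) break
  }
  hits <- scan_paired_sites(c(chr1 = g), left, right, 15, 100)
  expect_identical(nrow(hits), 0L)
})

test_that("the scanner agrees exactly with the scalar brute-force oracle", {
  set.seed(6)
  for (rep in 1:5) {
    left <- rand_genome(15); right <- rand_genome(15)
    pg <- make_planted_genome(rep + 10, 8000, left, right,
                              sample(20:60, 1))
    g <- pg$genome
    runs_l <- oracle_terminal_runs(g, left, TRUE)
    runs_r <- oracle_terminal_runs(g, rc_chr(right), FALSE)
    for (min_pm in c(8, 11, 15)) for (max_prod in c(50, 100, 200)) {
      got <- scan_paired_sites(c(chr1 = g), left, right, min_pm, max_prod)
      exp <- oracle_pair_scan(g, left, right, min_pm, max_prod,
                              runs_l, runs_r)
      expect_identical(got$left_start, as.integer(exp$left_start))
      expect_identical(got$right_start, as.integer(exp$right_start))
      expect_identical(got$product_size, as.integer(exp$product))
    }
  }
})

test_that("hit counts are monotone in stringency and product bound", {
  set.seed(8)
  left <- rand_genome(15); right <- rand_genome(15)
  pg <- make_planted_genome(21, 30000, left, right, 40)
  g <- c(chr1 = pg$genome)
  counts <- vapply(8:15, function(m)
    nrow(scan_paired_sites(g, left, right, m, 200)), integer(1))
  expect_true(all(diff(counts) <= 0))
  counts_p <- vapply(c(50, 100, 200), function(mp)
    nrow(scan_paired_sites(g, left, right, 8, mp)), integer(1))
  expect_true(all(diff(counts_p) >= 0))
})

test_that("scan_for_pair is orientation-symmetric and recovers on-target loci", {
  pf <- planted_family(31)
  pair <- talen_pair(pf$left_seq, pf$right_seq, 12, 20)
  genome <- stats::setNames(pf$family$sequence, "chrX")
  hits <- scan_for_pair(genome, pair, 8, 100)
  starts <- pf$family$copies$start[pf$family$copies$gene != "pseudo"] + 150
  expect_true(all(starts %in% hits$left_start))
  # the FokI-symmetric site (right arm on the plus strand, left arm on
  # the minus strand downstream) is still found, via the RL orientation
  set.seed(40)
  swapped <- paste0(pf$right_seq,
                    paste(rep("G", 16), collapse = ""), rc_chr(pf$left_seq))
  g2 <- rand_genome(5000)
  substr(g2, 2001, 2000 + nchar(swapped)) <- swapped
  h2 <- scan_for_pair(c(chrZ = g2), pair, 15, 100)
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$orientation, "RL")
})

test_that("input validation: N never matches and bad parameters error", {
  g <- c(chr1 = "ACGTACGTNNNNACGTACGTACGTACGTACGTACGTACGTACGT")
  expect_error(scan_paired_sites(g, "ACGT", "ACGT", 5, 100), "exceeds")
  expect_error(scan_paired_sites(c(chr1 = "ACGTX"), "ACGT", "ACGT", 4, 100),
               "outside")
  # a genome of N only can never host a hit
  gn <- c(chr1 = paste(rep("N", 100), collapse = ""))
  expect_identical(nrow(scan_paired_sites(gn, "ACGTACGT", "ACGTACGT",
                                          8, 100)), 0L)
})

test_that("reverse-complementing the genome mirrors hit coordinates", {
  set.seed(9)
  left <- rand_genome(15); right <- rand_genome(15)
  pg <- make_planted_genome(51, 10000, left, right, 30)
  n <- nchar(pg$genome)
  fwd <- scan_paired_sites(c(chr1 = pg$genome), left, right, 15, 100)
  rev <- scan_paired_sites(c(chr1 = rc_chr(pg$genome)), left, right, 15, 100)
  # the planted site appears once in one orientation scan each way when
  # arms are swapped left<->right under reverse complement
  rev_sw <- scan_paired_sites(c(chr1 = rc_chr(pg$genome)), right, left,
                              15, 100)
  expect_identical(nrow(fwd), 1L)
  expect_identical(nrow(rev_sw), 1L)
  # mirrored coordinate: left_start maps to n - right_end
  expect_identical(rev_sw$left_start, n - fwd$right_end)
  expect_identical(rev_sw$product_size, fwd$product_size)
})
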