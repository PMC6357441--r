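# Hand-built alignment fixtures: reads are constructed directly from a
# reference with known gaps, so the caller's output is fully predictable.
mk_reads <- function(reference, starts, cigars, seqs = NULL) {
  if (is.null(seqs)) seqs <- strrep("A", 50)
  data.frame(qname = sprintf("r%03d", seq_along(starts)), strand = "+",
             rname = "chr1", pos = starts, cigar = cigars,
             seq = rep_len(seqs, length(starts)), stringsAsFactors = FALSE)
}

test_that("a planted deletion at depth is called once with the exact size", {
  fam <- make_paralog_family(1, copy_labels = c("H2Afb3", "Gm14920",
                                                "H2Afb2"))
  hap <- talenko:::engineer_founder(fam, c(5L, 10L, 64L))
  gw <- apply_edits_to_sequence(fam, hap)
  reads <- simulate_reads(gw, sim_params(seed = 1, coverage = 30))
  calls <- call_indels(reads, fam$sequence)
  dels <- calls[calls$vtype == "DEL", ]
  expect_identical(nrow(dels), 3L)
  expect_setequal(dels$size, c(5L, 10L, 64L))
  truth_pos <- vapply(gw$ops, function(o) o$ref_pos - 1L, integer(1))
  expect_true(all(vapply(dels$pos, function(p)
    any(abs(truth_pos - p) <= 1L), logical(1))))
})

test_that("gap-free alignments yield no calls and unsorted input errors", {
  ref <- rand_genome(2000, seed = 2)
  reads <- mk_reads(ref, c(10L, 50L, 90L), rep("50M", 3))
  expect_identical(nrow(call_indels(reads, ref, min_support = 1)), 0L)
  bad <- mk_reads(ref, c(90L, 10L), rep("50M", 2))
  expect_error(call_indels(bad, ref), "sorted")
  empty <- mk_reads(ref, 10L, "50M")[0, ]
  expect_identical(nrow(call_indels(empty, ref)), 0L)
})

test_that("nearby deletions are merged or kept apart by the tolerance rule", {
  ref <- rand_genome(500, seed = 3)
  # two distinct deletions 5 bp apart (anchors 100 and 105), same size
  cigars <- c(rep("50M3D50M", 3), rep("55M3D45M", 3))
  reads <- mk_reads(ref, rep(51L, 6), cigars)
  calls <- call_indels(reads, ref, min_support = 2, merge_tolerance = 2)
  expect_identical(nrow(calls), 2L)
  expect_setequal(calls$pos, c(100L, 105L))
  # at tolerance 5 the same evidence merges into one call
  merged <- call_indels(reads, ref, min_support = 2, merge_tolerance = 5)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$support, 6L)
})

test_that("VCF-style ref/alt strings are anchored on the reference", {
  ref <- rand_genome(300, seed = 4)
  reads <- mk_reads(ref, rep(11L, 4), rep("40M6D60M", 4))
  call <- call_indels(reads, ref, min_support = 3)
  expect_identical(call$vtype, "DEL")
  expect_identical(call$pos, 50L)
  expect_identical(call$ref, substr(ref, 50, 56))
  expect_identical(call$alt, substr(ref, 50, 50))
  expect_identical(nchar(call$ref) - nchar(call$alt), call$size)
  ins <- mk_reads(ref, rep(11L, 4), rep("40M4I60M", 4),
                  seqs = strrep("C", 104))
  ic <- call_indels(ins, ref, min_support = 3)
  expect_identical(ic$vtype, "INS")
  expect_identical(ic$alt, paste0(substr(ref, 50, 50), "CCCC"))
})

test_that("soft-clipped reads re-anchor to recover deletions too large for D ops", {
  fam <- make_paralog_family(5, copy_len = 1000, flank_len = 600,
                             n_copies = 2, with_pseudogene = FALSE)
  genes <- functional_copies(fam)
  al <- stats::setNames(list(list(edit_event(genes[1], "deletion", 300,
                                             del_len = 400L)), list()),
                        genes)
  gw <- apply_edits_to_sequence(fam, al)
  reads <- simulate_reads(gw, sim_params(seed = 5, coverage = 40,
                                         max_del_in_cigar = 100L))
  expect_false(any(grepl("D", reads$cigar, fixed = TRUE)))
  calls <- call_indels(reads, fam$sequence)
  dels <- calls[calls$vtype == "DEL", ]
  expect_identical(nrow(dels), 1L)
  expect_identical(dels$size, 400L)
  expect_identical(dels$pos, gw$ops[[1]]$ref_pos - 1L)
})

test_that("genotype codes follow the allele-fraction thresholds", {
  calls <- data.frame(chrom = "c", pos = c(100L, 300L, 500L),
                      ref = "AT", alt = "A", vtype = "DEL", size = 1L,
                      support = c(30L, 15L, 4L),
                      spanning = c(30L, 30L, 30L),
                      quality = 200, genotype_code = NA_character_,
                      stringsAsFactors = FALSE)
  gt <- assign_genotype(calls)$genotype_code
  expect_identical(gt, c("1/1", "0/1", "no_call"))
  # fraction exactly 1 and 0.5
  expect_identical(assign_genotype(calls[1, ],
                                   allele_fraction = 1)$genotype_code, "1/1")
  expect_identical(assign_genotype(calls[1, ],
                                   allele_fraction = 0.5)$genotype_code,
                   "0/1")
  # zero spanning reads: no call, not an error
  nc <- calls[1, ]; nc$spanning <- 0L
  expect_identical(assign_genotype(nc)$genotype_code, "no_call")
})

test_that("two distinct alt sizes at one site genotype as 1/2", {
  calls <- data.frame(chrom = "c", pos = c(100L, 101L),
                      ref = c("ATT", "ATTT"), alt = "A", vtype = "DEL",
                      size = c(2L, 3L), support = c(15L, 14L),
                      spanning = c(30L, 30L), quality = 150,
                      genotype_code = NA_character_,
                      stringsAsFactors = FALSE)
  gt <- assign_genotype(calls)$genotype_code
  expect_identical(gt, c("1/2", "1/2"))
  # second allele het while the first is absent: 0/2
  calls2 <- calls
  calls2$support <- c(2L, 14L)
  gt2 <- assign_genotype(calls2)$genotype_code
  expect_identical(gt2[2], "0/2")
})

test_that("quality filtering is a monotone threshold on the support score", {
  calls <- data.frame(chrom = "c", pos = 1:6 * 100L, ref = "AT", alt = "A",
                      vtype = "DEL", size = 1L, support = 1:6 * 5L,
                      spanning = 40L, quality = c(50, 100, 150, 200, 250, 250),
                      genotype_code = "0/1", stringsAsFactors = FALSE)
  expect_identical(nrow(quality_filter(calls, 100)), 5L)
  expect_identical(quality_filter(calls, 100)$quality[1], 100)
  expect_identical(nrow(quality_filter(calls, 0)), 6L)
  survivors <- vapply(seq(0, 300, by = 25), function(q)
    nrow(quality_filter(calls, q)), integer(1))
  expect_true(all(diff(survivors) <= 0))
})

test_that("noisy error-free-free genomes produce no false calls at support 3", {
  # base errors at 0.005 with min_support 3: substitutions never imitate
  # indel evidence, so the call set stays empty across replicates
  fam <- make_paralog_family(6, copy_len = 300, flank_len = 200,
                             n_copies = 2, with_pseudogene = FALSE)
  empty <- stats::setNames(rep(list(list()), 2), functional_copies(fam))
  gw <- apply_edits_to_sequence(fam, empty)
  for (s in 1:10) {
    reads <- simulate_reads(gw, sim_params(seed = s, coverage = 25,
                                           base_error_rate = 0.005))
    calls <- call_indels(reads, fam$sequence, min_support = 3)
    expect_identical(nrow(calls), 0L)
  }
})
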