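calls_df <- function(pos, vtype = "DEL", size = 5L, gt = "0/1",
                     chrom = "chr1", ref = "ATTTTT", alt = "A",
                     truth_id = NA_character_) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vtype = vtype, size = as.integer(size), quality = 200,
             sample = "s", generation = 1L, genotype_code = gt,
             truth_id = truth_id, stringsAsFactors = FALSE)
}

test_that("strain filtering removes exactly the panel-matched calls", {
  reg <- make_variant_registry(1, n_strain = 20, n_induced = 10,
                               panel_omit_frac = 0)
  panel <- strain_panel(reg)
  calls <- calls_df(reg$pos, vtype = reg$vtype, size = reg$size,
                    ref = reg$ref, alt = reg$alt, chrom = reg$chrom,
                    truth_id = reg$id)
  sf <- strain_filter(calls, panel)
  expect_identical(nrow(sf$retained) + nrow(sf$removed), nrow(calls))
  expect_setequal(sf$removed$truth_id, reg$id[reg$origin == "strain"])
  expect_setequal(sf$retained$truth_id, reg$id[reg$origin == "induced"])
  # trivial panels
  expect_identical(nrow(strain_filter(calls, panel[0, ])$retained),
                   nrow(calls))
  expect_identical(nrow(strain_filter(calls[0, ], panel)$retained), 0L)
})

test_that("indel matching tolerates one base of left-alignment slack", {
  reg <- make_variant_registry(2, n_strain = 10, n_induced = 0,
                               panel_omit_frac = 0)
  panel <- strain_panel(reg)
  dels <- reg[reg$vtype == "DEL", ]
  shifted <- calls_df(dels$pos + 1L, vtype = "DEL", size = dels$size,
                      chrom = dels$chrom, truth_id = dels$id)
  expect_identical(nrow(strain_filter(shifted, panel)$retained), 0L)
  # a different size does not match even at the same position
  resized <- calls_df(dels$pos, vtype = "DEL", size = dels$size + 5L,
                      chrom = dels$chrom, truth_id = dels$id)
  expect_identical(nrow(strain_filter(resized, panel)$removed), 0L)
  # SNVs match exactly, never +/- 1
  snv_panel <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                          vtype = "SNV", size = 0L)
  snv_call <- calls_df(101L, vtype = "SNV", size = 0L, ref = "A", alt = "G")
  expect_identical(nrow(strain_filter(snv_call, snv_panel)$removed), 0L)
})

test_that("mismatched panel coordinate systems are refused, not lifted over", {
  panel <- data.frame(chrom = "chr1", pos = 1L, ref = "AT", alt = "A",
                      vtype = "DEL", size = 1L)
  attr(panel, "coord_system") <- "0-based"
  expect_error(strain_filter(calls_df(1L), panel), "coordinate system")
})

test_that("zygosity partition counts every category and the het sum rule", {
  calls <- calls_df(1:8 * 100L,
                    gt = c("0/1", "0/1", "1/2", "1/1", "1/1", "1/1",
                           "1/1", "1/1"))
  z <- zygosity_partition(calls)
  expect_identical(sum(z$counts), 8L)
  expect_identical(z$het_total, 3L)          # 0/1 + 0/2 + 1/2
  expect_identical(unname(z$counts["1/1"]), 5L)
  z10 <- zygosity_partition(calls_df(1:10 * 50L, gt = "0/1"))
  expect_identical(z10$het_total, 10L)
  z0 <- zygosity_partition(calls_df(100L)[0, ])
  expect_identical(sum(z0$counts), 0L)
  expect_identical(z0$het_total, 0L)
})

test_that("generation intersection keeps shared variants and shrinks monotonically", {
  a <- calls_df(c(100L, 200L, 300L))
  b <- calls_df(c(100L, 201L, 400L))   # 201 matches 200 within slack
  c3 <- calls_df(c(100L, 500L))
  expect_identical(intersect_generations(list(a, a))$pos, a$pos)
  expect_identical(nrow(intersect_generations(list(a, calls_df(900L)))), 0L)
  expect_setequal(intersect_generations(list(a, b))$pos, c(100L, 200L))
  expect_identical(intersect_generations(list(a, b, c3))$pos, 100L)
  # order independence (up to the representative coordinates)
  k1 <- nrow(intersect_generations(list(a, b, c3)))
  k2 <- nrow(intersect_generations(list(c3, b, a)))
  expect_identical(k1, k2)
  expect_error(intersect_generations(list(a)), "two generations")
})

test_that("the dilution likelihoods follow the absorbing 50% chain", {
  r <- dilution_test(c("present", "present", "present"),
                     in_strain_panel = TRUE)
  expect_equal(r$lik_induced, 0.125)
  expect_identical(r$lik_strain, 1)
  expect_identical(r$classification, "strain_variant")
  # persistent but unexplained by the panel: must be validated
  r2 <- dilution_test(c("present", "present", "present"),
                      in_strain_panel = FALSE)
  expect_identical(r2$classification, "needs_validation")
  r3 <- dilution_test(c("present", "absent", "absent"),
                      in_strain_panel = FALSE)
  expect_equal(r3$lik_induced, 0.25)   # 0.5 * 0.5 * 1
  expect_identical(r3$classification, "induced_candidate")
  r4 <- dilution_test(c("present", "absent", "present"), FALSE)
  expect_identical(r4$lik_induced, 0)
  expect_identical(r4$classification, "inconsistent")
  # missing generations contribute no factor
  r5 <- dilution_test(c("present", "missing", "present"), FALSE)
  expect_equal(r5$lik_induced, 0.25)
  # retention is configurable
  r6 <- dilution_test(c("present", "present"), TRUE, retention = 0.9)
  expect_equal(r6$lik_induced, 0.81)
  expect_error(dilution_test("present", TRUE), "two generations")
  expect_error(dilution_test(c("present", "odd"), TRUE), "invalid")
})

test_that("validation regions centre the variant and predict amplicon sizes", {
  genome <- c(chr1 = rand_genome(5000, seed = 10))
  v <- calls_df(2500L, vtype = "DEL", size = 10L)
  r <- design_validation_regions(v, genome)
  expect_identical(r$wt_size, 350L)
  expect_identical(r$mut_size, 340L)
  expect_false(r$clipped); expect_false(r$oversized)
  expect_true(r$start < 2500 && r$end > 2500)
  # region near the contig start is clipped and flagged
  r2 <- design_validation_regions(calls_df(10L, size = 2L), genome)
  expect_true(r2$clipped)
  expect_identical(r2$start, 0L)
  # an SNV changes nothing in size
  r3 <- design_validation_regions(calls_df(2500L, vtype = "SNV", size = 0L),
                                  genome)
  expect_identical(r3$wt_size, r3$mut_size)
  # a deletion larger than the admissible range is flagged, not dropped
  r4 <- design_validation_regions(calls_df(2500L, size = 600L,
                                           ref = "A", alt = "A"), genome)
  expect_true(r4$oversized)
  expect_error(design_validation_regions(calls_df(9999L), genome), "bounds")
})

test_that("gel distinguishability has a sharp resolution threshold", {
  expect_identical(compare_amplicons(350, 345), "distinguishable")
  expect_identical(compare_amplicons(350, 340), "distinguishable")
  expect_identical(compare_amplicons(350, 350), "indistinguishable")
  expect_identical(compare_amplicons(350, 346), "indistinguishable")
  expect_identical(compare_amplicons(350, 346, resolution = 4),
                   "distinguishable")
})
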