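fixture_path <- function() {
  system.file("extdata", "founder_genotypes.tsv", package = "talenko")
}

test_that("table-notation genotypes parse into typed allele descriptors", {
  m <- parse_genotype("X^∆5+286^ Y", "male")
  expect_length(m$alleles, 1L)
  expect_identical(m$alleles[[1]]$kind, "delins")
  expect_identical(m$alleles[[1]]$del_len, 5L)
  expect_identical(m$alleles[[1]]$ins_len, 286L)
  f <- parse_genotype("X^∆22^ X^∆160^", "female")
  expect_identical(vapply(f$alleles, `[[`, integer(1), "del_len"),
                   c(22L, 160L))
  wt <- parse_genotype("XX (wt)", "female")
  expect_length(wt$alleles, 2L)
  expect_true(all(vapply(wt$alleles, `[[`, character(1), "kind") == "wt"))
  na <- parse_genotype("No successful PCR amplification.", "female")
  expect_true(na$failed_amplification)
  # both Unicode deltas are accepted
  expect_identical(parse_genotype("X^Δ10^ Y", "male")$alleles[[1]]$del_len,
                   10L)
  # substitution alleles and chimera tags survive parsing
  s <- parse_genotype("X^C/T, A/G^ Y", "male")
  expect_identical(s$alleles[[1]]$kind, "subst")
  ch <- parse_genotype("X^∆12^ X^∆12^ Chimera of b/∆/c", "female")
  expect_identical(ch$chimera_tag, "Chimera of b/∆/c")
})

test_that("malformed genotypes fail loudly, naming the offending token", {
  expect_error(parse_genotype("X^∆x^ Y", "male"), "malformed")
  expect_error(parse_genotype("X^∆5^", "male"), "plus Y")
  expect_error(parse_genotype("X^∆5^ Y", "female"), "two X alleles")
  expect_error(parse_genotype("X^∆5^ garbage Y", "male"), "malformed")
})

test_that("parse and format are mutually inverse over the packaged table", {
  df <- read.table(fixture_path(), sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (i in seq_len(nrow(df))) {
    for (g in c("H2Afb3", "Gm14920", "H2Afb2")) {
      r1 <- parse_genotype(df[[g]][i], df$sex[i])
      r2 <- parse_genotype(format_genotype(r1), df$sex[i])
      expect_identical(r2, r1, info = paste(df$pup_id[i], g))
    }
  }
})

test_that("the packaged founder table shows the all-or-nothing outcome", {
  recs <- read_genotype_table(fixture_path())
  s <- founder_summary(recs)
  expect_identical(s$n_total, 19L)
  expect_identical(s$n_modified_all_genes, 9L)
  expect_identical(s$n_unmodified, 10L)
  expect_identical(s$n_partial, 0L)
  expect_identical(s$n_with_failed_amp, 2L)
  expect_identical(s$n_modified_all_genes + s$n_unmodified + s$n_partial,
                   s$n_total)
})

test_that("founder summary definitions react to constructed edge cases", {
  wt_pup <- list(pup_id = "p1", sex = "male", genes = list(
    g1 = parse_genotype("XY (wt)", "male"),
    g2 = parse_genotype("XY (wt)", "male")))
  part <- list(pup_id = "p2", sex = "male", genes = list(
    g1 = parse_genotype("XY (wt)", "male"),
    g2 = parse_genotype("X^∆5^ Y", "male")))
  s <- founder_summary(list(wt_pup, part))
  expect_identical(s$n_unmodified, 1L)
  expect_identical(s$n_partial, 1L)
  # failed amplification flips between evidence-of-modification and missing
  failed <- list(pup_id = "p3", sex = "male", genes = list(
    g1 = parse_genotype("No successful PCR amplification", "male"),
    g2 = parse_genotype("X^∆5^ Y", "male")))
  expect_identical(founder_summary(list(failed))$n_modified_all_genes, 1L)
  expect_identical(founder_summary(list(failed),
                                   failed_amp_policy = "missing")$n_modified_all_genes,
                   1L)
  mixed <- list(pup_id = "p4", sex = "male", genes = list(
    g1 = parse_genotype("No successful PCR amplification", "male"),
    g2 = parse_genotype("XY (wt)", "male")))
  expect_identical(founder_summary(list(mixed))$n_partial, 1L)
  expect_identical(founder_summary(list(mixed),
                                   failed_amp_policy = "missing")$n_unmodified,
                   1L)
  expect_error(founder_summary(list()), "empty")
})

test_that("amplification logic flags fusions only when both specifics fail", {
  amp <- function(s1, s2, mixed) data.frame(
    forward_gene = c("gm14920", "H2afb2", "gm14920"),
    reverse_gene = c("gm14920", "H2afb2", "H2afb2"),
    success = c(s1, s2, mixed), stringsAsFactors = FALSE)
  # the observed pattern: both specific pairs fail, mixed succeeds
  cand <- infer_chimera_from_amplification(amp(FALSE, FALSE, TRUE))
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$gene_5prime, "gm14920")
  expect_identical(cand$gene_3prime, "H2afb2")
  # exhaustive truth table of the inference rule
  for (s1 in c(TRUE, FALSE)) for (s2 in c(TRUE, FALSE))
    for (mx in c(TRUE, FALSE)) {
      n <- nrow(infer_chimera_from_amplification(amp(s1, s2, mx)))
      expect_identical(n, as.integer(!s1 && !s2 && mx),
                       info = sprintf("s1=%s s2=%s mx=%s", s1, s2, mx))
    }
})

test_that("fusion junctions are located with exact microhomology accounting", {
  # hand-built 60-mer amplicon sharing a 3-nt microhomology at the
  # junction; boundary bases are fixed so the homology cannot extend
  set.seed(21)
  mh <- "GCA"
  left <- paste0(rand_genome(27), "A")
  right <- paste0("G", rand_genome(28))
  A <- paste0(left, mh, "T", rand_genome(39))
  B <- paste0(rand_genome(36), "C", mh, right)
  amp <- paste0(left, mh, right)
  j <- locate_fusion_junction(amp, A, B, min_anchor = 15)
  o <- oracle_junction(amp, A, B, 15)
  expect_identical(j$microhomology_len, 3L)
  expect_identical(j$microhomology_len, o$mh)
  expect_identical(j$junction_deletion_len, o$del)
  expect_identical(j$junction_deletion_len,
                   nchar(A) + nchar(B) - nchar(amp))
  # an amplicon that is pure gene A has no B-side anchor
  Bfar <- paste0(rand_genome(60), "CCCCCCCCCCCCCCC")
  expect_error(locate_fusion_junction(A, A, Bfar, 15), "decomposition")
})

test_that("simulated fusions are recovered end to end from their amplicons", {
  pf <- planted_family(77)
  pair <- talen_pair(pf$left_seq, pf$right_seq, 12, 20)
  params <- sim_params(seed = 8, fusion_prob = 1, founder_edit_prob = 1)
  n_checked <- 0
  for (d in 1:40) {
    al <- apply_talen_edits(pf$family, pair, params, draw = d)
    for (g in names(al)) for (ev in al[[g]]) {
      if (ev$kind != "fusion" || !is.null(attr(ev, "fusion_partner_of")))
        next
      A <- family_copy_seq(pf$family, ev$gene)
      B <- family_copy_seq(pf$family, ev$partner_gene)
      cand <- infer_chimera_from_amplification(
        amplification_matrix_from_alleles(al))
      expect_identical(cand$gene_5prime, ev$gene)
      expect_identical(cand$gene_3prime, ev$partner_gene)
      amp <- fuse_sequences(A, B, ev$position, ev$partner_keep_from + 1)
      j <- locate_fusion_junction(amp, A, B)
      expect_identical(j$junction_deletion_len, ev$del_len)
      expect_identical(j$microhomology_len, ev$microhomology_len)
      expect_lte(abs(j$gene_a_keep - ev$position), ev$microhomology_len)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 20)
})
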