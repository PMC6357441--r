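#' Simulation parameter container
#'
#' One validated bundle for every stochastic element of the synthetic-data
#' module. Defaults encode the study conditions of a multi-copy TALEN
#' knockout experiment: roughly half of born pups carry edits
#' (`founder_edit_prob = 9/19`), editing is all-or-nothing across copies,
#' deletions are small (shifted-geometric, mean 15 nt), insertions rare,
#' paralog fusions occur in a minority of edited founders, junctions show
#' 2-6 nt of terminal microhomology, and about a quarter of G1 animals
#' show mosaicism.
#'
#' @param seed Mandatory integer seed; there is no implicit entropy.
#' @param founder_edit_prob Probability a founder is edited at all.
#' @param all_or_nothing If `TRUE`, an edited founder carries edits in
#'   every functional copy; an unedited founder in none.
#' @param del_len_mean Mean NHEJ deletion length (nt, shifted geometric).
#' @param ins_prob Probability an edit also carries an insertion.
#' @param long_ins_prob Probability an insertion is long (~hundreds nt),
#'   mimicking a rare large templated insertion.
#' @param fusion_prob Probability an edited founder carries a paralog
#'   fusion replacing two copies.
#' @param microhomology_range Length-2 integer vector, admissible junction
#'   microhomology (nt).
#' @param mosaic_prob Probability a founder edit is mosaic.
#' @param n_strain_variants Number of fixed strain-difference variants.
#' @param n_induced_offtargets Number of founder-heterozygous induced
#'   off-target variants (0 for the negative-control study design).
#' @param read_len Simulated read length (nt).
#' @param coverage Mean read depth.
#' @param base_error_rate Per-base substitution error rate in reads.
#' @param fp_indel_rate Spurious indel calls per Mb in the call simulator.
#' @param size_error_sd SD of the (rounded, sign-preserving) Gaussian
#'   perturbation applied to reported indel sizes.
#' @param max_del_in_cigar Deletions larger than this are represented as
#'   soft-clipped reads rather than in-read `D` operations.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(seed,
                       founder_edit_prob = 9 / 19,
                       all_or_nothing = TRUE,
                       del_len_mean = 15,
                       ins_prob = 0.1,
                       long_ins_prob = 0.05,
                       fusion_prob = 0.15,
                       microhomology_range = c(2L, 6L),
                       mosaic_prob = 22 / 78,
                       n_strain_variants = 50L,
                       n_induced_offtargets = 0L,
                       read_len = 100L,
                       coverage = 30,
                       base_error_rate = 0,
                       fp_indel_rate = 0,
                       size_error_sd = 0,
                       max_del_in_cigar = 100L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  p <- list(seed = as.integer(seed),
            founder_edit_prob = founder_edit_prob,
            all_or_nothing = isTRUE(all_or_nothing),
            del_len_mean = del_len_mean,
            ins_prob = ins_prob,
            long_ins_prob = long_ins_prob,
            fusion_prob = fusion_prob,
            microhomology_range = as.integer(microhomology_range),
            mosaic_prob = mosaic_prob,
            n_strain_variants = as.integer(n_strain_variants),
            n_induced_offtargets = as.integer(n_induced_offtargets),
            read_len = as.integer(read_len),
            coverage = coverage,
            base_error_rate = base_error_rate,
            fp_indel_rate = fp_indel_rate,
            size_error_sd = size_error_sd,
            max_del_in_cigar = as.integer(max_del_in_cigar))
  probs <- c(p$founder_edit_prob, p$ins_prob, p$long_ins_prob,
             p$fusion_prob, p$mosaic_prob, p$base_error_rate)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (p$coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  if (p$read_len <= 0L) stop("read_len must be > 0", call. = FALSE)
  if (length(p$microhomology_range) != 2L ||
      p$microhomology_range[1] > p$microhomology_range[2])
    stop("microhomology_range must be (min, max) with min <= max",
         call. = FALSE)
  if (p$del_len_mean < 1) stop("del_len_mean must be >= 1", call. = FALSE)
  structure(p, class = "sim_params")
}
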