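#' Construct an individual
#'
#' X-linked genotypes are stored per haplotype because the gene family
#' sits on one X chromosome and is transmitted as a unit (no
#' recombination within the family is modelled). Males carry one X
#' haplotype, females two. Autosomal variants are stored as id sets:
#' `background_het_variants` (heterozygous, founder-induced candidates)
#' and `strain_variants` (fixed strain differences, always transmitted).
#'
#' @param id Individual id.
#' @param sex `"male"` or `"female"`.
#' @param generation Integer >= 0 (0 = founder).
#' @param x_haplotypes List of 1 (male) or 2 (female) haplotypes; each is
#'   a named list over gene labels of `edit_event` lists (empty = wt).
#' @param background_het_variants,strain_variants Character id vectors.
#' @param bg_mosaic Named numeric carrier fraction per background
#'   variant id (defaults to 1 = constitutive).
#' @param sire,dam Parent ids (`NA` for founders/mates).
#' @return A list of class `individual`.
#' @export
new_individual <- function(id, sex, generation, x_haplotypes,
                           background_het_variants = character(0),
                           strain_variants = character(0),
                           bg_mosaic = NULL, sire = NA_character_,
                           dam = NA_character_) {
  sex <- match.arg(sex, c("male", "female"))
  n_exp <- if (sex == "male") 1L else 2L
  if (length(x_haplotypes) != n_exp)
    stop(sprintf("%s must carry exactly %d X haplotype(s)", sex, n_exp),
         call. = FALSE)
  if (is.null(bg_mosaic))
    bg_mosaic <- stats::setNames(rep(1, length(background_het_variants)),
                                 background_het_variants)
  structure(list(id = id, sex = sex, generation = as.integer(generation),
                 x_haplotypes = x_haplotypes,
                 background_het_variants = background_het_variants,
                 strain_variants = strain_variants,
                 bg_mosaic = bg_mosaic, sire = sire, dam = dam),
            class = "individual")
}

## An unedited mate of the given sex sharing the line's fixed strain
## variants.
wt_mate <- function(id, sex, generation, genes, strain_variants) {
  empty <- stats::setNames(rep(list(list()), length(genes)), genes)
  n <- if (sex == "male") 1L else 2L
  new_individual(id, sex, generation, rep(list(empty), n),
                 strain_variants = strain_variants)
}

## Retain mosaic edits of a transmitted haplotype with probability equal
## to their carrier fraction; survivors become constitutive.
settle_mosaic_haplotype <- function(hap) {
  lapply(hap, function(evs) {
    kept <- list()
    for (ev in evs) {
      if (ev$mosaic_fraction >= 1 || stats::runif(1) < ev$mosaic_fraction) {
        ev$mosaic_fraction <- 1
        kept[[length(kept) + 1L]] <- ev
      }
    }
    kept
  })
}

#' Produce one offspring under Mendelian X-linked transmission
#'
#' The mother transmits one of her two X haplotypes uniformly; the father
#' transmits his X to daughters and his Y to sons. Each maternal
#' autosomal heterozygous variant is transmitted with probability 0.5
#' (times its carrier fraction if mosaic, after which it is constitutive
#' in carriers); fixed strain variants are transmitted to every
#' offspring.
#'
#' @param mother,father `individual`s (mother female, father male).
#' @param id Offspring id.
#' @param sex Offspring sex, or `NULL` to draw uniformly.
#' @return An `individual` of generation `mother$generation + 1`.
#' @export
transmit_offspring <- function(mother, father, id, sex = NULL) {
  if (mother$sex != "female" || father$sex != "male")
    stop("pedigree construction requires a female dam and a male sire",
         call. = FALSE)
  if (is.null(sex)) sex <- sample(c("male", "female"), 1L)
  mat <- settle_mosaic_haplotype(
    mother$x_haplotypes[[sample.int(2L, 1L)]])
  haps <- if (sex == "female") list(mat, father$x_haplotypes[[1L]])
          else list(mat)
  bg <- character(0)
  for (v in mother$background_het_variants) {
    frac <- mother$bg_mosaic[[v]]
    if (is.null(frac) || is.na(frac)) frac <- 1
    if (stats::runif(1) < 0.5 * frac) bg <- c(bg, v)
  }
  bg <- union(bg, father$background_het_variants[
    stats::runif(length(father$background_het_variants)) < 0.5])
  new_individual(id, sex, mother$generation + 1L, haps,
                 background_het_variants = bg,
                 strain_variants = union(mother$strain_variants,
                                         father$strain_variants),
                 sire = father$id, dam = mother$id)
}

#' Simulate a backcross pedigree from an edited founder
#'
#' Implements the study's breeding design: mutant females are crossed to
#' wild-type males of the same strain for `n_generations`, so any
#' founder-heterozygous variant is diluted by 50% per generation while
#' fixed strain differences persist in every animal. Under
#' `founder_cross_then_backcross` generation 1 is produced from the
#' founder crossed to a wild-type mate first (founder of either sex),
#' after which female carriers are backcrossed as above.
#'
#' @param founder An `individual` (generation 0).
#' @param scheme `"backcross_female_mut"` (founder must be female) or
#'   `"founder_cross_then_backcross"`.
#' @param n_generations Number of generations to breed (>= 1).
#' @param params A [sim_params()] bundle (seeds the draw).
#' @param n_offspring Litter size per generation.
#' @param stream RNG stream tag, so replicate lines are independent.
#' @return List of `individual`s: the founder followed by all offspring,
#'   generation by generation. The line is continued through a female of
#'   the previous litter carrying the edited X where one exists.
#' @export
simulate_pedigree <- function(founder, scheme = c("backcross_female_mut",
                                                  "founder_cross_then_backcross"),
                              n_generations = 3L, params, n_offspring = 8L,
                              stream = "pedigree") {
  scheme <- match.arg(scheme)
  stopifnot(n_generations >= 1L, n_offspring >= 1L)
  if (scheme == "backcross_female_mut" && founder$sex != "female")
    stop("backcross_female_mut requires a female founder", call. = FALSE)
  genes <- names(founder$x_haplotypes[[1L]])
  with_seed(derive_seed(params$seed, stream), {
    out <- list(founder)
    mother <- if (founder$sex == "female") founder else NULL
    father <- if (founder$sex == "male") founder else NULL
    for (g in seq_len(n_generations)) {
      if (is.null(mother))
        mother <- wt_mate(sprintf("dam_G%d", g - 1L), "female", g - 1L,
                          genes, founder$strain_variants)
      if (is.null(father))
        father <- wt_mate(sprintf("sire_G%d", g - 1L), "male", g - 1L,
                          genes, founder$strain_variants)
      litter <- lapply(seq_len(n_offspring), function(k)
        transmit_offspring(mother, father,
                           sprintf("%s_G%d_%d", founder$id, g, k)))
      out <- c(out, litter)
      # continue the line through an edited female; sire is always wt
      females <- Filter(function(x) x$sex == "female", litter)
      carrier <- Filter(function(x) any(lengths(x$x_haplotypes[[1L]]) > 0L) ||
                          any(lengths(x$x_haplotypes[[2L]]) > 0L), females)
      nxt <- if (length(carrier)) carrier[[1L]]
             else if (length(females)) females[[1L]] else NULL
      if (is.null(nxt) && g < n_generations)
        stop("pedigree construction error: no female available to continue ",
             "the line at generation ", g, call. = FALSE)
      mother <- nxt
      father <- NULL
    }
    out
  })
}

#' Persistence of founder background variants over replicate descent lines
#'
#' Breeds `n_lines` independent single-offspring descent lines from the
#' founder (each birth produced by [transmit_offspring()], offspring
#' forced female so the line is unbroken) and reports, per founder
#' heterozygous variant, the fraction of lines in which it is still
#' present at generation `n_generations`. The analytic expectation under
#' Mendelian backcross dilution is `0.5^n_generations`.
#'
#' @param founder A female `individual` with background het variants.
#' @param n_lines Number of replicate lines.
#' @param n_generations Meioses per line.
#' @param params A [sim_params()] bundle (seeds the draw).
#' @return Named numeric: per-variant presence fraction at the final
#'   generation.
#' @export
simulate_descent_lines <- function(founder, n_lines, n_generations, params) {
  stopifnot(founder$sex == "female", n_generations >= 1L)
  genes <- names(founder$x_haplotypes[[1L]])
  counts <- stats::setNames(numeric(length(founder$background_het_variants)),
                            founder$background_het_variants)
  with_seed(derive_seed(params$seed, "descent_lines"), {
    for (l in seq_len(n_lines)) {
      mother <- founder
      for (g in seq_len(n_generations)) {
        father <- wt_mate("sire", "male", g - 1L, genes,
                          founder$strain_variants)
        mother <- transmit_offspring(mother, father,
                                     sprintf("L%d_G%d", l, g),
                                     sex = "female")
      }
      hit <- intersect(names(counts), mother$background_het_variants)
      counts[hit] <- counts[hit] + 1
    }
  })
  counts / n_lines
}

#' Write a pedigree table (TSV: id, sex, generation, sire, dam)
#' @param individuals List of `individual`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree_tsv <- function(individuals, path) {
  df <- do.call(rbind, lapply(individuals, function(x)
    data.frame(id = x$id, sex = x$sex, generation = x$generation,
               sire = x$sire, dam = x$dam, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
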