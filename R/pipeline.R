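## Allowed configuration keys per block; unknown keys are rejected before
## any stage runs.
CONFIG_SCHEMA <- list(
  top = c("seed", "outdir", "sim", "design", "scan", "call", "dilution"),
  sim = c("n_copies", "copy_len", "min_identity", "flank_len",
          "with_pseudogene", "copy_labels", "engineered_del_sizes",
          "founder_edit_prob", "all_or_nothing", "del_len_mean",
          "ins_prob", "long_ins_prob", "fusion_prob",
          "microhomology_range", "mosaic_prob", "n_strain_variants",
          "n_induced_offtargets", "read_len", "coverage",
          "base_error_rate", "fp_indel_rate", "size_error_sd",
          "max_del_in_cigar", "n_offspring"),
  design = c("arm_len", "spacer_range", "require_5prime_T",
             "max_mismatch_per_arm"),
  scan = c("min_perfect_match", "max_product"),
  call = c("min_support", "min_quality", "merge_tolerance"),
  dilution = c("retention", "generations")
)

config_error <- function(...) {
  stop(structure(class = c("talenko_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Validate and complete a pipeline run configuration
#'
#' Accepts a YAML file path or a nested list, rejects unknown keys, and
#' fills defaults: a three-copy family (>= 92% identity) with engineered
#' deletions of 5, 10 and 64 nt; paired-site scanning at a minimum
#' perfect match of 8 nt and maximum product of 100 bp; an indel quality
#' cutoff of 100; and a 3-generation backcross dilution at 50% retention.
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) config_error("config must be a list or YAML path")
  unknown <- setdiff(names(config), CONFIG_SCHEMA$top)
  if (length(unknown))
    config_error("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (blk in c("sim", "design", "scan", "call", "dilution")) {
    bad <- setdiff(names(config[[blk]]), CONFIG_SCHEMA[[blk]])
    if (length(bad))
      config_error("unknown key(s) in '", blk, "': ",
                   paste(bad, collapse = ", "))
  }
  defaults <- list(
    seed = 1L, outdir = NULL,
    sim = list(n_copies = 3L, copy_len = 500L, min_identity = 0.92,
               flank_len = 500L, with_pseudogene = TRUE,
               copy_labels = NULL, engineered_del_sizes = c(5L, 10L, 64L),
               n_strain_variants = 50L, n_induced_offtargets = 0L,
               read_len = 100L, coverage = 30, base_error_rate = 0,
               fp_indel_rate = 0, size_error_sd = 0, n_offspring = 10L),
    design = list(arm_len = 15L, spacer_range = c(12L, 20L),
                  require_5prime_T = FALSE, max_mismatch_per_arm = 3L),
    scan = list(min_perfect_match = 8L, max_product = 100L),
    call = list(min_support = 3L, min_quality = 100, merge_tolerance = 3L),
    dilution = list(retention = 0.5, generations = 3L)
  )
  out <- utils::modifyList(defaults, config)
  if (is.null(out$seed)) config_error("seed is mandatory")
  if (out$dilution$generations < 2L)
    config_error("dilution requires at least 2 generations")
  structure(out, class = c("run_config", "list"))
}

## The sim_params() subset of the sim block.
config_sim_params <- function(config) {
  keep <- intersect(names(config$sim),
                    names(formals(sim_params)))
  do.call(sim_params, c(list(seed = config$seed), config$sim[keep]))
}

## Deterministic engineered founder: a female homozygous for one fixed
## deletion per functional copy (sizes from the config), centred on the
## family-wide cut sites when a pair is supplied.
engineer_founder <- function(family, sizes, pair = NULL) {
  fun <- functional_copies(family)
  stopifnot(length(sizes) == length(fun))
  cuts <- if (!is.null(pair)) find_cut_sites(family, pair)[fun]
          else stats::setNames(rep(family$copy_len %/% 2L, length(fun)), fun)
  hap <- stats::setNames(lapply(seq_along(fun), function(i) {
    cut <- cuts[[i]]
    if (is.na(cut)) cut <- family$copy_len %/% 2L
    pos <- cut - sizes[i] %/% 2L
    pos <- max(5L, min(pos, family$copy_len - sizes[i] - 5L))
    list(edit_event(fun[i], "deletion", position = pos,
                    del_len = sizes[i]))
  }), fun)
  hap
}

## Content hash of the canonicalised config (md5 hex string). Output
## paths do not alter the scientific content, so outdir is excluded.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

stage_error <- function(stage, e) {
  stop(structure(class = c("talenko_stage_error", "error", "condition"),
                 list(message = sprintf("stage '%s' failed: %s", stage,
                                        conditionMessage(e)), call = NULL)))
}

#' Run the full simulate-design-scan-call-dilute workflow
#'
#' Orchestrates every stage on synthetic data with full truth records:
#' (1) simulate a paralog family, an engineered founder female
#' (homozygous for one deletion per copy), the autosomal background
#' (fixed strain variants plus optional induced off-target candidates)
#' and a backcross pedigree; (2) design a family-wide TALEN pair over the
#' copies; (3) scan the genome for paired binding sites under relaxed
#' matching; (4) per generation, sequence one edited male in silico, call
#' indels from the gapped alignments, genotype and quality-filter them,
#' and merge in the simulated autosomal calls; (5) strain-filter,
#' intersect across generations and classify each survivor under the
#' dilution model; (6) evaluate the final candidate list against truth.
#' Reruns with the same config are reproducible; a manifest records the
#' seed and a config hash.
#'
#' @param config A [run_config()] (or list/YAML path coercible to one).
#' @return List of class `run_report` with per-stage summaries, the final
#'   candidate table, the truth evaluation and the manifest. When
#'   `config$outdir` is set, FASTA/VCF/TSV/BED/JSON artifacts are written
#'   there.
#' @export
run_end_to_end <- function(config = list()) {
  config <- run_config(config)
  outdir <- config$outdir
  art <- function(name) if (is.null(outdir)) NULL else file.path(outdir, name)
  if (!is.null(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  params <- config_sim_params(config)

  ## stage: simulate ---------------------------------------------------
  sim <- tryCatch({
    family <- make_paralog_family(
      config$seed, n_copies = config$sim$n_copies,
      copy_len = config$sim$copy_len,
      min_identity = config$sim$min_identity,
      flank_len = config$sim$flank_len,
      with_pseudogene = config$sim$with_pseudogene,
      copy_labels = config$sim$copy_labels)
    registry <- make_variant_registry(
      config$seed, n_strain = params$n_strain_variants,
      n_induced = params$n_induced_offtargets)
    list(family = family, registry = registry)
  }, error = function(e) stage_error("simulate", e))
  family <- sim$family; registry <- sim$registry

  ## stage: design -----------------------------------------------------
  pair <- tryCatch({
    cand <- enumerate_pairs(family, arm_len = config$design$arm_len,
                            spacer_range = config$design$spacer_range,
                            require_5prime_T = config$design$require_5prime_T,
                            genes = functional_copies(family)[1])
    if (!nrow(cand)) stop("no candidate pairs in the first copy")
    chosen <- NULL
    for (i in seq_len(nrow(cand))) {
      p <- talen_pair(cand$left_seq[i], cand$right_seq[i],
                      config$design$spacer_range[1],
                      config$design$spacer_range[2])
      cls <- classify_specificity(p, family,
                                  config$design$max_mismatch_per_arm)
      if (cls$class == "family_wide") { chosen <- p; break }
    }
    if (is.null(chosen))
      chosen <- talen_pair(cand$left_seq[1], cand$right_seq[1],
                           config$design$spacer_range[1],
                           config$design$spacer_range[2])
    chosen
  }, error = function(e) stage_error("design", e))

  ## stage: scan -------------------------------------------------------
  hits <- tryCatch({
    genome <- stats::setNames(family$sequence, family$chromosome_name)
    scan_for_pair(genome, pair,
                  min_perfect_match = config$scan$min_perfect_match,
                  max_product = config$scan$max_product)
  }, error = function(e) stage_error("scan", e))

  ## stage: pedigree + call -------------------------------------------
  gens <- config$dilution$generations
  called <- tryCatch({
    founder_hap <- engineer_founder(family, config$sim$engineered_del_sizes,
                                    pair)
    founder <- new_individual(
      "founder", "female", 0L, list(founder_hap, founder_hap),
      background_het_variants = registry$id[registry$origin == "induced"],
      strain_variants = registry$id[registry$origin == "strain"])
    pedigree <- simulate_pedigree(founder, "backcross_female_mut",
                                  n_generations = gens, params = params,
                                  n_offspring = config$sim$n_offspring)
    calls_by_gen <- vector("list", gens)
    sequenced <- character(gens)
    for (g in seq_len(gens)) {
      gen_inds <- Filter(function(x) x$generation == g, pedigree)
      males <- Filter(function(x) x$sex == "male", gen_inds)
      edited <- Filter(function(x) any(lengths(x$x_haplotypes[[1L]]) > 0L),
                       males)
      animal <- if (length(edited)) edited[[1L]]
                else if (length(males)) males[[1L]] else gen_inds[[1L]]
      sequenced[g] <- animal$id
      gw <- apply_edits_to_sequence(family, animal$x_haplotypes[[1L]])
      reads <- simulate_reads(gw, params, rname = family$chromosome_name,
                              stream = paste0("reads/", animal$id))
      x_calls <- call_indels(reads, family$sequence,
                             min_support = config$call$min_support,
                             merge_tolerance = config$call$merge_tolerance)
      x_calls <- assign_genotype(x_calls)
      truth_ops <- gw$ops
      x_calls$truth_id <- vapply(seq_len(nrow(x_calls)), function(i) {
        for (op in truth_ops) {
          if (abs((op$ref_pos - 1L) - x_calls$pos[i]) <= 2L)
            return(paste0("xedit:", op$gene, ":", op$kind))
        }
        NA_character_
      }, character(1))
      x_calls$sample <- rep(animal$id, nrow(x_calls))
      x_calls$generation <- rep(g, nrow(x_calls))
      auto_calls <- simulate_variant_calls(animal, family, params, registry,
                                           stream = animal$id,
                                           include_x_edits = FALSE)
      shared <- intersect(names(x_calls), names(auto_calls))
      merged <- rbind(x_calls[, shared, drop = FALSE],
                      auto_calls[, shared, drop = FALSE])
      calls_by_gen[[g]] <- quality_filter(merged, config$call$min_quality)
      if (!is.null(outdir))
        write_vcf(calls_by_gen[[g]], art(sprintf("calls_G%d.vcf", g)),
                  sample = animal$id)
    }
    list(calls_by_gen = calls_by_gen, sequenced = sequenced,
         pedigree = pedigree)
  }, error = function(e) stage_error("call", e))

  ## stage: dilute -----------------------------------------------------
  dilute <- tryCatch({
    panel <- strain_panel(registry)
    filtered <- lapply(called$calls_by_gen, function(x)
      strain_filter(x, panel)$retained)
    zyg <- lapply(filtered, zygosity_partition)
    common <- intersect_generations(filtered)
    report <- dilution_report_table(common, filtered, panel,
                                    retention = config$dilution$retention)
    genome <- stats::setNames(family$sequence, family$chromosome_name)
    regions <- if (nrow(common[common$chrom == family$chromosome_name, ]))
      design_validation_regions(
        common[common$chrom == family$chromosome_name, , drop = FALSE],
        genome) else NULL
    list(panel = panel, filtered = filtered, zygosity = zyg,
         common = common, report = report, regions = regions)
  }, error = function(e) stage_error("dilute", e))

  ## stage: evaluate ---------------------------------------------------
  truth <- rbind(
    registry[, c("chrom", "pos", "vtype", "size", "id", "origin")],
    do.call(rbind, lapply(
      edits_to_chrom_ops(family, engineer_founder(
        family, config$sim$engineered_del_sizes, pair)),
      function(op) data.frame(chrom = family$chromosome_name,
                              pos = op$ref_pos - 1L, vtype = "DEL",
                              size = op$del,
                              id = paste0("xedit:", op$gene, ":", op$kind),
                              origin = "engineered",
                              stringsAsFactors = FALSE))))
  evaluation <- evaluate_against_truth(dilute$common, truth)

  manifest <- list(package = "talenko",
                   version = as.character(utils::packageVersion("talenko")),
                   seed = config$seed, config_hash = config_hash(config),
                   sequenced = called$sequenced)
  if (!is.null(outdir)) {
    write_family_fasta(family, art("family.fasta"))
    write_pedigree_tsv(called$pedigree, art("pedigree.tsv"))
    utils::write.table(hits, art("paired_site_hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(hits)) write_hits_bed(hits, art("paired_site_hits.bed"))
    utils::write.table(dilute$report, art("dilution_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, art("truth.json"), auto_unbox = TRUE,
                         digits = NA)
    jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  structure(list(family = family, pair = pair, scan_hits = hits,
                 registry = registry, calls_by_gen = called$calls_by_gen,
                 zygosity = dilute$zygosity, common = dilute$common,
                 dilution = dilute$report, regions = dilute$regions,
                 evaluation = evaluation, manifest = manifest),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("talenko end-to-end run (seed", x$manifest$seed, ")\n")
  cat("  paired-site scan hits:", nrow(x$scan_hits), "\n")
  cat("  calls per generation:",
      paste(vapply(x$calls_by_gen, nrow, integer(1)), collapse = ", "), "\n")
  cat("  cross-generation candidates:", nrow(x$common), "\n")
  cat("  candidate classes:",
      if (nrow(x$dilution)) paste(names(table(x$dilution$classification)),
                                  table(x$dilution$classification),
                                  collapse = ", ") else "none", "\n")
  cat("  truth evaluation: TP", x$evaluation$TP, "FP", x$evaluation$FP,
      "FN", x$evaluation$FN, "\n")
  invisible(x)
}

#' Evaluate called variants against a simulation truth set
#'
#' Matches by chromosome, type and position within +/- 1 bp. Reports TP
#' (matched calls), FP (unmatched calls), FN (unmatched truth records)
#' and the absolute size error per TP.
#'
#' @param called data.frame with chrom, pos, vtype, size.
#' @param truth data.frame with chrom, pos, vtype, size (and optionally
#'   id); or a path to a truth JSON written by [run_end_to_end()].
#' @return List: TP, FP, FN, size_errors (integer vector).
#' @export
evaluate_against_truth <- function(called, truth) {
  if (is.character(truth)) {
    if (!file.exists(truth)) stop("missing truth file: ", truth,
                                  call. = FALSE)
    truth <- as.data.frame(jsonlite::read_json(truth, simplifyVector = TRUE))
  }
  if (!nrow(called))
    return(list(TP = 0L, FP = 0L, FN = nrow(truth),
                size_errors = integer(0)))
  matched_truth <- rep(FALSE, nrow(truth))
  tp <- 0L; fp <- 0L; size_errors <- integer(0)
  for (i in seq_len(nrow(called))) {
    hit <- which(truth$chrom == called$chrom[i] &
                   truth$vtype == called$vtype[i] &
                   abs(truth$pos - called$pos[i]) <= 1L)
    if (length(hit)) {
      tp <- tp + 1L
      matched_truth[hit[1L]] <- TRUE
      size_errors <- c(size_errors,
                       abs(called$size[i] - truth$size[hit[1L]]))
    } else fp <- fp + 1L
  }
  list(TP = tp, FP = fp, FN = sum(!matched_truth), size_errors = size_errors)
}
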