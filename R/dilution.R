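## Key helpers for +/-1-tolerant indel matching (left-alignment slack);
## SNVs match exactly.
match_one <- function(call, set) {
  same_chrom <- set$chrom == call$chrom
  if (call$vtype == "SNV") {
    same_chrom & set$pos == call$pos & set$ref == call$ref &
      set$alt == call$alt
  } else {
    same_chrom & set$vtype == call$vtype &
      abs(set$pos - call$pos) <= 1L & set$size == call$size
  }
}

#' Remove known strain-background variants from a call set
#'
#' Splits calls into those matching the strain panel (removed) and the
#' rest (retained). SNVs must match (chrom, pos, ref, alt) exactly;
#' indels tolerate +/- 1 bp of position at identical size, absorbing
#' left-alignment ambiguity between callers. The panel and the calls must
#' declare the same coordinate system; no silent lift-over is attempted.
#'
#' @param calls data.frame of variant calls.
#' @param panel Strain panel data.frame (chrom, pos, ref, alt, vtype,
#'   size), optionally carrying a `coord_system` attribute.
#' @param coord_system Coordinate system of `calls` (default "1-based").
#' @return List with `retained` and `removed`; their union is the input.
#' @export
strain_filter <- function(calls, panel, coord_system = "1-based") {
  pcs <- attr(panel, "coord_system")
  if (!is.null(pcs) && !identical(pcs, coord_system))
    stop("strain panel is in coordinate system '", pcs,
         "' but calls are '", coord_system, "'; refusing to match",
         call. = FALSE)
  if (!nrow(calls))
    return(list(retained = calls, removed = calls))
  if (!nrow(panel))
    return(list(retained = calls, removed = calls[0, , drop = FALSE]))
  hit <- vapply(seq_len(nrow(calls)), function(i)
    any(match_one(calls[i, ], panel)), logical(1))
  list(retained = calls[!hit, , drop = FALSE],
       removed = calls[hit, , drop = FALSE])
}

#' Tabulate calls by zygosity code
#'
#' Counts calls per genotype category and reports the heterozygous total
#' as the 0/1 + 0/2 + 1/2 sum (the heterozygous-polymorphism summation
#' used when screening indels for a dilution pattern).
#'
#' @param calls data.frame with `genotype_code`.
#' @return List: `counts` (named vector over 0/0, 0/1, 0/2, 1/1, 1/2,
#'   2/2, no_call) and `het_total`.
#' @export
zygosity_partition <- function(calls) {
  codes <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2", "no_call")
  counts <- stats::setNames(integer(length(codes)), codes)
  if (nrow(calls)) {
    t <- table(factor(calls$genotype_code, levels = codes))
    counts[names(t)] <- as.integer(t)
  }
  list(counts = counts,
       het_total = unname(counts["0/1"] + counts["0/2"] + counts["1/2"]))
}

#' Intersect call sets across generations
#'
#' Returns the variants present in every generation: same chromosome and
#' type, position within +/- 1 bp, identical size. The result is reported
#' in the coordinates of the first generation; its cardinality is
#' non-increasing as generations are added, and the operation is
#' associative and order-independent.
#'
#' @param calls_by_generation List (length >= 2) of call data.frames.
#' @return data.frame: the subset of the first generation's calls found
#'   in all others.
#' @export
intersect_generations <- function(calls_by_generation) {
  if (length(calls_by_generation) < 2L)
    stop("need at least two generations to intersect", call. = FALSE)
  base <- calls_by_generation[[1L]]
  if (!nrow(base)) return(base)
  keep <- rep(TRUE, nrow(base))
  for (g in 2L:length(calls_by_generation)) {
    other <- calls_by_generation[[g]]
    if (!nrow(other)) return(base[0, , drop = FALSE])
    keep <- keep & vapply(seq_len(nrow(base)), function(i)
      any(match_one(base[i, ], other)), logical(1))
  }
  out <- base[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a variant's cross-generation persistence pattern
#'
#' Formalises the backcross dilution argument as an absorbing chain: a
#' founder-heterozygous (induced) variant is retained with probability
#' `retention` (default 0.5) at each generation and, once lost from the
#' line, stays lost; a fixed strain difference is present in every
#' generation with probability 1. The likelihood of the observed
#' presence pattern is computed under both models, and the variant is
#' classified as `strain_variant` (persistent and in the panel),
#' `needs_validation` (persistent but *not* in the panel — only wet
#' validation can separate an un-catalogued strain difference from an
#' undiluted artifact), `induced_candidate` (a pattern with absorbing
#' absence), or `inconsistent` (reappears after absence; impossible
#' under either model).
#'
#' @param presence Character vector over generations, each `"present"`,
#'   `"absent"` or `"missing"` (missing = uninformative, likelihood
#'   factor 1).
#' @param in_strain_panel Is the variant in the strain panel?
#' @param retention Per-generation transmission probability in (0, 1).
#' @param variant_id Optional id copied into the report.
#' @return List of class `dilution_report`: variant_id, presence,
#'   in_strain_panel, lik_induced, lik_strain, classification.
#' @export
#' @examples
#' dilution_test(c("present", "present", "present"), in_strain_panel = TRUE)
#' dilution_test(c("present", "absent", "absent"), in_strain_panel = FALSE)
dilution_test <- function(presence, in_strain_panel, retention = 0.5,
                          variant_id = NA_character_) {
  if (length(presence) < 2L)
    stop("presence pattern must cover at least two generations",
         call. = FALSE)
  if (retention <= 0 || retention >= 1)
    stop("retention must lie strictly between 0 and 1", call. = FALSE)
  bad <- setdiff(unique(presence), c("present", "absent", "missing"))
  if (length(bad))
    stop("invalid presence state(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  lik_induced <- 1
  state <- "present"   # the founder carried it
  for (p in presence) {
    if (p == "missing") next
    if (state == "present") {
      lik_induced <- lik_induced *
        if (p == "present") retention else (1 - retention)
      state <- p
    } else {        # absorbed: absent thereafter
      if (p == "present") { lik_induced <- 0; break }
    }
  }
  observed <- presence[presence != "missing"]
  all_present <- length(observed) > 0L && all(observed == "present")
  lik_strain <- if (all_present) 1 else 0
  classification <- if (lik_induced == 0 && lik_strain == 0) {
    "inconsistent"
  } else if (lik_strain == 1) {
    if (isTRUE(in_strain_panel)) "strain_variant" else "needs_validation"
  } else {
    "induced_candidate"
  }
  structure(list(variant_id = variant_id, presence = presence,
                 in_strain_panel = isTRUE(in_strain_panel),
                 lik_induced = lik_induced, lik_strain = lik_strain,
                 classification = classification),
            class = "dilution_report")
}

#' @export
print.dilution_report <- function(x, ...) {
  cat(sprintf("variant %s: [%s] -> %s (L_induced=%.4g, L_strain=%g)\n",
              x$variant_id, paste(x$presence, collapse = ", "),
              x$classification, x$lik_induced, x$lik_strain))
  invisible(x)
}

#' Dilution reports for an intersected candidate list
#'
#' Builds per-variant presence patterns over the per-generation call sets
#' and runs [dilution_test()] on each candidate.
#'
#' @param candidates data.frame of candidate variants (typically the
#'   output of [intersect_generations()] on strain-filtered calls).
#' @param calls_by_generation List of per-generation call data.frames.
#' @param panel Strain panel (for the in-panel flag).
#' @param retention Per-generation retention probability.
#' @return data.frame: one row per candidate with likelihoods and class.
#' @export
dilution_report_table <- function(candidates, calls_by_generation, panel,
                                  retention = 0.5) {
  if (!nrow(candidates)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      vtype = character(0), size = integer(0),
                      truth_id = character(0), lik_induced = numeric(0),
                      lik_strain = numeric(0),
                      classification = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    v <- candidates[i, ]
    presence <- vapply(calls_by_generation, function(g)
      if (nrow(g) && any(match_one(v, g))) "present" else "absent",
      character(1))
    rep <- dilution_test(presence,
                         in_strain_panel = nrow(panel) > 0L &&
                           any(match_one(v, panel)),
                         retention = retention,
                         variant_id = if ("truth_id" %in% names(v))
                           v$truth_id else NA_character_)
    data.frame(chrom = v$chrom, pos = v$pos, vtype = v$vtype,
               size = v$size,
               truth_id = if ("truth_id" %in% names(v)) v$truth_id
                          else NA_character_,
               lik_induced = rep$lik_induced, lik_strain = rep$lik_strain,
               classification = rep$classification,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Design PCR validation regions around candidate variants
#'
#' Centres a region of the conventional amplicon size (350 bp, clamped
#' into `target_len_range`) on each variant, clips it at contig ends
#' (flagging clipped regions), flags variants larger than the maximum
#' range as oversized rather than dropping them, and predicts the mutant
#' amplicon size as wt size - deletion + insertion — the size difference
#' a gel comparison would resolve.
#'
#' @param variants data.frame with chrom, pos (1-based), vtype, size.
#' @param genome Named character vector of contig sequences.
#' @param target_len_range Length-2 admissible region size (bp).
#' @return data.frame: chrom, start, end (0-based half-open), length,
#'   wt_size, mut_size, clipped, oversized.
#' @export
design_validation_regions <- function(variants, genome,
                                      target_len_range = c(300L, 450L)) {
  target <- max(target_len_range[1], min(350L, target_len_range[2]))
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    contig_len <- nchar(genome[[v$chrom]])
    if (is.null(contig_len) || v$pos < 1L || v$pos > contig_len)
      stop("variant outside genome bounds: ", v$chrom, ":", v$pos,
           call. = FALSE)
    del <- if (v$vtype == "DEL") v$size else 0L
    ins <- if (v$vtype == "INS") v$size else 0L
    len <- max(target, del + 2L)                 # region must span the variant
    oversized <- len > target_len_range[2]
    centre <- v$pos + del %/% 2L
    start0 <- centre - len %/% 2L                # 0-based half-open
    end0 <- start0 + len
    clipped <- FALSE
    if (start0 < 0L) { start0 <- 0L; clipped <- TRUE }
    if (end0 > contig_len) { end0 <- contig_len; clipped <- TRUE }
    wt <- end0 - start0
    data.frame(chrom = v$chrom, start = start0, end = end0, length = wt,
               wt_size = wt, mut_size = wt - del + ins,
               clipped = clipped, oversized = oversized,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Can two amplicon sizes be told apart on a gel?
#'
#' Distinguishable when the absolute size difference reaches
#' `resolution` nt — a 7% polyacrylamide gel resolves differences down to
#' about 5 nt in the 300-450 bp range.
#'
#' @param wt_size,mut_size Amplicon sizes (bp, > 0).
#' @param resolution Smallest resolvable difference (nt, default 5).
#' @return `"distinguishable"` or `"indistinguishable"` (vectorised).
#' @export
compare_amplicons <- function(wt_size, mut_size, resolution = 5L) {
  stopifnot(all(wt_size > 0), all(mut_size > 0))
  ifelse(abs(wt_size - mut_size) >= resolution,
         "distinguishable", "indistinguishable")
}
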