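#' Build a registry of autosomal background variants
#'
#' Generates the fixed strain-difference panel and (optionally) a set of
#' founder-heterozygous induced off-target candidates, all placed on one
#' synthetic autosome. Strain variants are fixed differences of the
#' breeding line against the reference; a configurable fraction of them
#' is withheld from the published panel, mimicking the gap between the
#' sequenced substrain and the catalogued one (the situation that leaves
#' a residue of un-subtracted, validation-requiring indels).
#'
#' @param seed Integer seed.
#' @param n_strain Number of fixed strain variants.
#' @param n_induced Number of induced founder-het off-target variants
#'   (0 for the negative-control design).
#' @param autosome_len Synthetic autosome length (nt).
#' @param panel_omit_frac Fraction of strain variants absent from the
#'   panel (default 0.1).
#' @param chrom Chromosome label.
#' @return data.frame of class `variant_registry`: id, chrom, pos (1-based),
#'   ref, alt, vtype, size, origin (`strain`/`induced`), in_panel; with
#'   attribute `autosome_len`.
#' @export
make_variant_registry <- function(seed, n_strain = 50L, n_induced = 0L,
                                  autosome_len = 2e6, panel_omit_frac = 0.1,
                                  chrom = "chr1_sim") {
  n <- n_strain + n_induced
  with_seed(derive_seed(seed, "registry"), {
    pos <- sort(sample.int(autosome_len - 100L, n))
    # keep loci well apart so +/-1 matching never confuses two variants
    while (any(diff(pos) < 50L)) {
      pos <- sort(sample.int(autosome_len - 100L, n))
    }
    rows <- lapply(seq_len(n), function(i) {
      origin <- if (i <= n_strain) "strain" else "induced"
      # induced variants are indels (nuclease repair products); strain
      # differences are a mix of SNVs and indels
      vtype <- if (origin == "induced") {
        sample(c("DEL", "INS"), 1L, prob = c(0.85, 0.15))
      } else {
        sample(c("SNV", "DEL", "INS"), 1L, prob = c(0.5, 0.35, 0.15))
      }
      anchor <- sample(DNA_BASES, 1L)
      if (vtype == "SNV") {
        ref <- anchor; alt <- sample(setdiff(DNA_BASES, anchor), 1L)
        size <- 0L
      } else if (vtype == "DEL") {
        size <- stats::rgeom(1L, 1 / 8) + 1L
        ref <- paste0(anchor, random_dna(size)); alt <- anchor
      } else {
        size <- stats::rgeom(1L, 1 / 6) + 1L
        ref <- anchor; alt <- paste0(anchor, random_dna(size))
      }
      data.frame(id = sprintf("%s%04d", ifelse(origin == "strain", "sv", "iv"), i),
                 chrom = chrom, pos = pos[i], ref = ref, alt = alt,
                 vtype = vtype, size = size, origin = origin,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$in_panel <- df$origin == "strain" &
      stats::runif(n) >= panel_omit_frac
    attr(df, "autosome_len") <- autosome_len
    class(df) <- c("variant_registry", class(df))
    df
  })
}

#' The published strain panel of a registry
#'
#' @param registry A `variant_registry`.
#' @return data.frame keyed by (chrom, pos, ref, alt) with vtype/size,
#'   attribute `coord_system = "1-based"`.
#' @export
strain_panel <- function(registry) {
  panel <- registry[registry$in_panel,
                    c("chrom", "pos", "ref", "alt", "vtype", "size")]
  rownames(panel) <- NULL
  attr(panel, "coord_system") <- "1-based"
  panel
}

## Perturb a reported indel size: rounded Normal(0, sd) error, clipped to
## +/- (true size - 1) so the sign (and hence the type) is preserved.
perturb_size <- function(size, sd) {
  if (sd <= 0 || size <= 1L) return(size)
  e <- round(stats::rnorm(length(size), 0, sd))
  e <- pmax(pmin(e, size - 1L), -(size - 1L))
  as.integer(size + e)
}

#' Simulate noisy variant calls for one individual
#'
#' Emulates the output of an alignment-plus-calling pipeline without
#' simulating reads: every variant the individual truly carries is
#' emitted with its correct type, a reported size perturbed by a rounded,
#' sign-preserving Gaussian error (`size_error_sd`), and a quality score;
#' spurious indel calls are injected at `fp_indel_rate` per Mb with
#' random zygosity. The generating truth id rides along in the
#' `truth_id` column (`NA` for false positives) for downstream
#' evaluation.
#'
#' @param individual An `individual`.
#' @param family A `paralog_family` (to place X-linked edit calls).
#' @param params A [sim_params()] bundle.
#' @param registry A `variant_registry` for the autosomal background.
#' @param sample Sample label (defaults to the individual id).
#' @param stream RNG stream tag.
#' @param include_x_edits Emit calls for the X-linked engineered edits?
#'   Set `FALSE` when those loci are called from simulated reads instead,
#'   to avoid double counting.
#' @return data.frame of variant calls: chrom, pos, ref, alt, vtype,
#'   size, quality, sample, generation, genotype_code, truth_id.
#' @export
simulate_variant_calls <- function(individual, family, params, registry,
                                   sample = individual$id,
                                   stream = individual$id,
                                   include_x_edits = TRUE) {
  with_seed(derive_seed(params$seed, paste0("calls/", stream)), {
    rows <- list()
    emit <- function(chrom, pos, ref, alt, vtype, size, quality, gt, tid) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
        vtype = vtype, size = as.integer(size), quality = quality,
        sample = sample, generation = individual$generation,
        genotype_code = gt, truth_id = tid, stringsAsFactors = FALSE)
    }
    ## autosomal background: fixed strain variants (hom) + founder-het
    present <- c(stats::setNames(rep("1/1", length(individual$strain_variants)),
                                 individual$strain_variants),
                 stats::setNames(rep("0/1", length(individual$background_het_variants)),
                                 individual$background_het_variants))
    for (vid in names(present)) {
      v <- registry[registry$id == vid, ]
      if (nrow(v) != 1L) next
      size <- perturb_size(v$size, params$size_error_sd)
      ref <- v$ref; alt <- v$alt
      if (v$vtype == "DEL" && size != v$size)
        ref <- paste0(substr(ref, 1L, 1L), random_dna(size))
      if (v$vtype == "INS" && size != v$size)
        alt <- paste0(substr(alt, 1L, 1L), random_dna(size))
      emit(v$chrom, v$pos, ref, alt, v$vtype, size,
           round(stats::runif(1, 150, 250)), present[[vid]], vid)
    }
    ## X-linked engineered edits, mapped to chromosome coordinates
    hemi <- individual$sex == "male"
    seen <- character(0)
    if (include_x_edits) for (h in seq_along(individual$x_haplotypes)) {
      ops <- edits_to_chrom_ops(family, individual$x_haplotypes[[h]])
      for (op in ops) {
        key <- paste(op$ref_pos, op$del, nchar(op$ins))
        vtype <- if (op$del > 0L) "DEL" else "INS"
        size <- if (op$del > 0L) op$del else nchar(op$ins)
        gt <- if (hemi) "1/1" else if (key %in% seen) "1/1" else "0/1"
        if (!hemi && key %in% seen) {
          # second haplotype carries the same allele: upgrade to hom
          for (k in seq_along(rows)) {
            r <- rows[[k]]
            if (r$chrom == family$chromosome_name &&
                r$pos == op$ref_pos - 1L && r$size == size) {
              rows[[k]]$genotype_code <- "1/1"
            }
          }
          next
        }
        seen <- c(seen, key)
        anchor_pos <- op$ref_pos - 1L  # VCF anchored base before the event
        anchor <- substr(family$sequence, anchor_pos, anchor_pos)
        size_rep <- perturb_size(size, params$size_error_sd)
        if (vtype == "DEL") {
          ref <- paste0(anchor, substr(family$sequence, op$ref_pos,
                                       op$ref_pos + size_rep - 1L))
          alt <- anchor
        } else {
          ref <- anchor
          alt <- paste0(anchor, substr(op$ins, 1L, size_rep))
        }
        emit(family$chromosome_name, anchor_pos, ref, alt, vtype, size_rep,
             round(stats::runif(1, 150, 250)), gt,
             paste0("xedit:", op$gene, ":", op$kind))
      }
    }
    ## spurious calls at fp_indel_rate per Mb of the autosome
    mb <- attr(registry, "autosome_len") / 1e6
    n_fp <- stats::rpois(1L, params$fp_indel_rate * mb)
    if (n_fp > 0L) for (i in seq_len(n_fp)) {
      pos <- sample.int(attr(registry, "autosome_len") - 50L, 1L)
      size <- stats::rgeom(1L, 1 / 6) + 1L
      anchor <- sample(DNA_BASES, 1L)
      del <- stats::runif(1) < 0.7
      emit(registry$chrom[1L], pos,
           if (del) paste0(anchor, random_dna(size)) else anchor,
           if (del) anchor else paste0(anchor, random_dna(size)),
           if (del) "DEL" else "INS", size,
           round(stats::runif(1, 30, 250)),
           sample(c("0/1", "1/1"), 1L), NA_character_)
    }
    if (!length(rows)) return(empty_calls())
    df <- do.call(rbind, rows)
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

empty_calls <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), vtype = character(0), size = integer(0),
             quality = numeric(0), sample = character(0),
             generation = integer(0), genotype_code = character(0),
             truth_id = character(0), stringsAsFactors = FALSE)
}

#' Write variant calls as a VCF v4.2 subset
#'
#' CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO plus a GT sample column. The
#' truth id (when present) is carried in INFO as `TID=` so simulated
#' files remain self-evaluating.
#'
#' @param calls data.frame of calls (as from [simulate_variant_calls()]).
#' @param path Output path.
#' @param sample Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample = "sample1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=TID,Number=1,Type=String,Description=\"Simulation truth id\">",
               "##INFO=<ID=GEN,Number=1,Type=Integer,Description=\"Pedigree generation\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample, sep = "\t")), con)
  if (nrow(calls)) {
    info <- paste0(
      ifelse(is.na(calls$truth_id), "TID=.", paste0("TID=", calls$truth_id)),
      ";GEN=", calls$generation)
    writeLines(paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                     calls$quality, "PASS", info, "GT",
                     calls$genotype_code, sep = "\t"), con)
  }
  invisible(path)
}

#' Read the VCF subset written by [write_vcf()]
#'
#' @param path VCF path.
#' @return data.frame of calls in the package's column layout.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(empty_calls())
  f <- strsplit(body, "\t", fixed = TRUE)
  df <- do.call(rbind, lapply(f, function(x) {
    info <- strsplit(x[8], ";", fixed = TRUE)[[1]]
    tid <- sub("^TID=", "", grep("^TID=", info, value = TRUE)[1])
    gen <- sub("^GEN=", "", grep("^GEN=", info, value = TRUE)[1])
    ref <- x[4]; alt <- x[5]
    vtype <- if (nchar(ref) > nchar(alt)) "DEL"
             else if (nchar(alt) > nchar(ref)) "INS" else "SNV"
    data.frame(chrom = x[1], pos = as.integer(x[2]), ref = ref, alt = alt,
               vtype = vtype, size = abs(nchar(ref) - nchar(alt)),
               quality = as.numeric(x[6]), sample = NA_character_,
               generation = as.integer(gen),
               genotype_code = x[10],
               truth_id = if (identical(tid, ".")) NA_character_ else tid,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}
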