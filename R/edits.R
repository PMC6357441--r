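#' Construct an edit event
#'
#' One nuclease-induced repair outcome at a gene copy: a small deletion,
#' an insertion, a deletion-plus-insertion (delins), or a fusion joining
#' the 5' part of this gene to the 3' part of a partner paralog. A fusion
#' always loses sequence at the junction.
#'
#' @param gene Gene label carrying the event (for fusions, the 5' gene).
#' @param kind One of `"deletion"`, `"insertion"`, `"delins"`, `"fusion"`.
#' @param position 0-based offset within the gene of the first affected
#'   base (for fusions, the number of retained 5'-gene bases).
#' @param del_len Deleted length (nt; for fusions, total bases lost at
#'   the junction relative to the two parents).
#' @param ins_len,ins_seq Inserted length and sequence (`""` if none).
#' @param partner_gene Fusion partner (3' gene), fusions only.
#' @param partner_keep_from 0-based offset within the partner gene at
#'   which the retained 3' suffix begins (fusions only).
#' @param microhomology_len Exact terminal microhomology spanning a
#'   fusion junction (nt).
#' @param mosaic_fraction Carrier fraction in the individual the event
#'   arose in (1 = constitutive).
#' @return A list of class `edit_event`.
#' @export
edit_event <- function(gene, kind, position, del_len = 0L, ins_len = 0L,
                       ins_seq = "", partner_gene = NA_character_,
                       partner_keep_from = NA_integer_,
                       microhomology_len = 0L, mosaic_fraction = 1) {
  kind <- match.arg(kind, c("deletion", "insertion", "delins", "fusion"))
  del_len <- as.integer(del_len); ins_len <- as.integer(ins_len)
  if (kind == "deletion" && (del_len <= 0L || ins_len != 0L))
    stop("deletion requires del_len > 0 and ins_len = 0", call. = FALSE)
  if (kind == "insertion" && (ins_len <= 0L || del_len != 0L))
    stop("insertion requires ins_len > 0 and del_len = 0", call. = FALSE)
  if (kind == "delins" && (del_len <= 0L || ins_len <= 0L))
    stop("delins requires del_len > 0 and ins_len > 0", call. = FALSE)
  if (kind == "fusion") {
    if (is.na(partner_gene) || identical(partner_gene, gene))
      stop("fusion requires a distinct partner_gene", call. = FALSE)
    if (del_len <= 0L)
      stop("a fusion junction always loses sequence (del_len > 0)",
           call. = FALSE)
  }
  if (nchar(ins_seq) != ins_len)
    stop("ins_seq length must equal ins_len", call. = FALSE)
  structure(list(gene = gene, kind = kind, position = as.integer(position),
                 del_len = del_len, ins_len = ins_len, ins_seq = ins_seq,
                 partner_gene = partner_gene,
                 partner_keep_from = as.integer(partner_keep_from),
                 microhomology_len = as.integer(microhomology_len),
                 mosaic_fraction = mosaic_fraction),
            class = "edit_event")
}

## Best placement (minimum total Hamming mismatch) of a TALEN pair in one
## copy sequence. Returns list(i, spacer, mismatch) with i 1-based, or
## NULL when nothing within max_mismatch per arm.
find_pair_placement <- function(copy_seq, pair, max_mismatch = 3L) {
  al <- pair$arm_len
  right_site <- revcomp(pair$right_seq)
  L <- nchar(copy_seq)
  best <- NULL
  imax <- L - 2L * al - pair$spacer_min + 1L
  if (imax < 1L) return(NULL)
  for (i in seq_len(imax)) {
    dl <- hamming(substr(copy_seq, i, i + al - 1L), pair$left_seq)
    if (dl > max_mismatch) next
    for (s in pair$spacer_min:pair$spacer_max) {
      j <- i + al + s
      if (j + al - 1L > L) break
      dr <- hamming(substr(copy_seq, j, j + al - 1L), right_site)
      if (dr <= max_mismatch &&
          (is.null(best) || dl + dr < best$mismatch)) {
        best <- list(i = i, spacer = s, mismatch = dl + dr)
      }
    }
  }
  best
}

## 0-based cut offset within each copy that the pair can cleave
## (middle of the spacer); NA where the pair has no placement.
find_cut_sites <- function(family, pair, max_mismatch = 3L) {
  vapply(family$copies$gene, function(g) {
    pl <- find_pair_placement(family_copy_seq(family, g), pair, max_mismatch)
    if (is.null(pl)) return(NA_integer_)
    as.integer(pl$i - 1L + pair$arm_len + pl$spacer %/% 2L)
  }, integer(1))
}

#' Exact microhomology spanning a fusion junction
#'
#' For a fusion retaining `A[1..a]` then `B[b..]`, counts the bases that
#' could equally be attributed to either parent: the longest suffix of
#' the retained A prefix equal to the B bases immediately 5' of `b`, plus
#' the longest prefix of the retained B suffix equal to the A bases
#' immediately 3' of `a`.
#'
#' @param seq_a,seq_b Parent gene sequences.
#' @param a Retained 5'-parent length (bases).
#' @param b 1-based start of the retained 3'-parent suffix.
#' @return Integer microhomology length (>= 0).
#' @export
junction_microhomology <- function(seq_a, seq_b, a, b) {
  la <- nchar(seq_a)
  ca <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  k_left <- 0L
  while (a - k_left >= 1L && b - 1L - k_left >= 1L &&
         ca[a - k_left] == cb[b - 1L - k_left]) k_left <- k_left + 1L
  k_right <- 0L
  while (a + 1L + k_right <= la && b + k_right <= length(cb) &&
         ca[a + 1L + k_right] == cb[b + k_right]) k_right <- k_right + 1L
  k_left + k_right
}

## Draw a fusion event joining geneA (5') to geneB (3'). Junction
## positions are sampled near the two cut sites until the realised
## microhomology falls inside params$microhomology_range (bounded
## retries; the closest draw is kept as a fallback).
draw_fusion_event <- function(family, gene_a, gene_b, cut_a, cut_b, params) {
  seq_a <- family_copy_seq(family, gene_a)
  seq_b <- family_copy_seq(family, gene_b)
  # keep the junction well inside both copies so anchors always exist
  cut_a <- min(max(cut_a, 60L), nchar(seq_a) - 60L)
  cut_b <- min(max(cut_b, 60L), nchar(seq_b) - 60L)
  mh_rng <- params$microhomology_range
  best <- NULL
  for (try in seq_len(400L)) {
    del_a <- stats::rgeom(1L, 1 / 4) + 1L   # bases lost from A's 3' side
    del_b <- stats::rgeom(1L, 1 / 4)        # bases lost from B's 5' side
    a <- cut_a - del_a
    b <- cut_b + del_b + 1L                 # 1-based start of kept suffix
    if (a < 20L || b > nchar(seq_b) - 20L) next
    mh <- junction_microhomology(seq_a, seq_b, a, b)
    cand <- list(a = a, b = b, mh = mh,
                 del = (nchar(seq_a) - a) + (b - 1L))
    if (mh >= mh_rng[1] && mh <= mh_rng[2]) { best <- cand; break }
    if (is.null(best) ||
        min(abs(mh - mh_rng)) < min(abs(best$mh - mh_rng))) best <- cand
  }
  if (is.null(best)) stop("could not place fusion junction", call. = FALSE)
  edit_event(gene = gene_a, kind = "fusion", position = best$a,
             del_len = best$del, partner_gene = gene_b,
             partner_keep_from = best$b - 1L,
             microhomology_len = best$mh)
}

## One indel repair outcome at a 0-based cut offset.
draw_indel_event <- function(gene, cut, params) {
  d <- stats::rgeom(1L, 1 / params$del_len_mean) + 1L
  ins <- stats::runif(1) < params$ins_prob
  if (ins) {
    n <- if (stats::runif(1) < params$long_ins_prob)
      sample(200:300, 1L) else sample(1:10, 1L)
    s <- random_dna(n)
    edit_event(gene, "delins", position = cut - d %/% 2L,
               del_len = d, ins_len = n, ins_seq = s)
  } else {
    edit_event(gene, "deletion", position = cut - d %/% 2L, del_len = d)
  }
}

#' Simulate TALEN editing of a founder across a paralog family
#'
#' Draws one founder outcome. Under the all-or-nothing model the founder
#' either receives at least one edit in *every* functional copy (with
#' probability `founder_edit_prob`) or none at all; otherwise copies are
#' edited independently. With probability `fusion_prob` an edited founder
#' carries a paralog fusion that replaces two copies with a single
#' chimeric allele whose junction shows terminal microhomology within the
#' configured range. Deletion lengths follow a shifted geometric
#' distribution with mean `del_len_mean`; insertions occur with
#' probability `ins_prob`. Events may be mosaic (carrier fraction < 1)
#' with probability `mosaic_prob`.
#'
#' @param family A `paralog_family`.
#' @param pair A `talen_pair` with a cut site in at least one copy.
#' @param params A [sim_params()] bundle (its `seed` drives the draw; use
#'   different seeds for independent founders).
#' @param draw Integer draw index, so one `params` can generate many
#'   independent founders deterministically.
#' @param cuts Optional precomputed result of [find_cut_sites()] for this
#'   family/pair, to avoid rescanning when drawing many founders.
#' @return Named list over functional copies; each element is a list of
#'   `edit_event`s (empty = wild type). A fusion appears once, under its
#'   5' gene, and the partner copy's allele is the same fused molecule
#'   (its own list carries the marker event too, flagged by
#'   `attr(, "fusion_partner_of")`).
#' @export
apply_talen_edits <- function(family, pair, params, draw = 1L,
                              cuts = NULL) {
  if (is.null(cuts)) cuts <- find_cut_sites(family, pair)
  fun <- functional_copies(family)
  cuts <- cuts[fun]
  if (all(is.na(cuts)))
    stop("TALEN pair has no cut site in any gene copy", call. = FALSE)
  with_seed(derive_seed(params$seed, paste0("edits/", draw)), {
    alleles <- stats::setNames(vector("list", length(fun)), fun)
    edited <- if (params$all_or_nothing) {
      rep(stats::runif(1) < params$founder_edit_prob, length(fun))
    } else {
      stats::runif(length(fun)) < params$founder_edit_prob
    }
    names(edited) <- fun
    if (!any(edited)) return(alleles)
    fusion_genes <- character(0)
    if (stats::runif(1) < params$fusion_prob) {
      # adjacent edited copies with usable cut sites, 5' gene first
      ok <- fun[edited & !is.na(cuts)]
      if (length(ok) >= 2L) {
        i <- sample(length(ok) - 1L, 1L)
        ga <- ok[i]; gb <- ok[i + 1L]
        ev <- draw_fusion_event(family, ga, gb, cuts[[ga]], cuts[[gb]], params)
        if (stats::runif(1) < params$mosaic_prob)
          ev$mosaic_fraction <- stats::runif(1, 0.2, 0.8)
        alleles[[ga]] <- list(ev)
        marker <- ev
        attr(marker, "fusion_partner_of") <- ga
        alleles[[gb]] <- list(marker)
        fusion_genes <- c(ga, gb)
      }
    }
    for (g in setdiff(fun[edited], fusion_genes)) {
      cut <- cuts[[g]]
      if (is.na(cut)) cut <- as.integer(family$copy_len %/% 2L)
      ev <- draw_indel_event(g, cut, params)
      if (stats::runif(1) < params$mosaic_prob)
        ev$mosaic_fraction <- stats::runif(1, 0.2, 0.8)
      alleles[[g]] <- list(ev)
    }
    alleles
  })
}

## Convert per-gene edit events to chromosome-scale (ref_pos, del, ins)
## records. ref_pos is the 1-based position of the first affected base.
## A fusion becomes one large deletion spanning from the end of the kept
## 5'-gene prefix to the start of the kept partner suffix.
edits_to_chrom_ops <- function(family, alleles) {
  ops <- list()
  for (g in names(alleles)) {
    gstart <- family$copies$start[family$copies$gene == g]
    for (ev in alleles[[g]]) {
      if (!is.null(attr(ev, "fusion_partner_of"))) next  # partner marker
      if (ev$kind == "fusion") {
        pstart <- family$copies$start[family$copies$gene == ev$partner_gene]
        from <- gstart + ev$position + 1L        # first deleted base, 1-based
        to <- pstart + ev$partner_keep_from      # last deleted base, 1-based
        ops[[length(ops) + 1L]] <- list(
          ref_pos = from, del = to - from + 1L, ins = "",
          gene = g, kind = "fusion", truth = ev)
      } else {
        ops[[length(ops) + 1L]] <- list(
          ref_pos = gstart + ev$position + 1L,
          del = ev$del_len, ins = ev$ins_seq,
          gene = g, kind = ev$kind, truth = ev)
      }
    }
  }
  if (length(ops))
    ops <- ops[order(vapply(ops, `[[`, numeric(1), "ref_pos"))]
  ops
}

#' Apply edit events to a chromosome sequence
#'
#' Builds the edited haplotype plus the block map relating haplotype to
#' reference coordinates, which the read simulator uses to emit gapped
#' alignments against the *unedited* reference.
#'
#' @param family A `paralog_family` (provides the reference sequence and
#'   gene coordinates).
#' @param alleles Per-gene edit lists as returned by
#'   [apply_talen_edits()] (one haplotype's worth).
#' @return List of class `edited_haplotype`: `reference`, `haplotype`,
#'   `blocks` (data.frame hap_start/ref_start/len of matching segments,
#'   1-based), and `ops` (the chromosome-scale edit records).
#' @export
apply_edits_to_sequence <- function(family, alleles) {
  ref <- family$sequence
  ops <- edits_to_chrom_ops(family, alleles)
  hap_parts <- character(0)
  blocks <- list()
  cur_ref <- 1L; cur_hap <- 1L
  for (op in ops) {
    if (op$ref_pos < cur_ref)
      stop("overlapping edit events on one haplotype", call. = FALSE)
    mlen <- op$ref_pos - cur_ref
    if (mlen > 0L) {
      hap_parts <- c(hap_parts, substr(ref, cur_ref, op$ref_pos - 1L))
      blocks[[length(blocks) + 1L]] <-
        data.frame(hap_start = cur_hap, ref_start = cur_ref, len = mlen)
      cur_hap <- cur_hap + mlen
    }
    if (nzchar(op$ins)) {
      hap_parts <- c(hap_parts, op$ins)
      cur_hap <- cur_hap + nchar(op$ins)
    }
    cur_ref <- op$ref_pos + op$del
  }
  if (cur_ref <= nchar(ref)) {
    hap_parts <- c(hap_parts, substr(ref, cur_ref, nchar(ref)))
    blocks[[length(blocks) + 1L]] <-
      data.frame(hap_start = cur_hap, ref_start = cur_ref,
                 len = nchar(ref) - cur_ref + 1L)
  }
  structure(list(reference = ref,
                 haplotype = paste(hap_parts, collapse = ""),
                 blocks = do.call(rbind, blocks),
                 ops = ops),
            class = "edited_haplotype")
}
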