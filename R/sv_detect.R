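## Parse one CIGAR string into op/len vectors.
parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDS]", cigar))[[1]]
  list(len = as.integer(sub("[MIDS]$", "", m)),
       op = sub("^[0-9]+", "", m))
}

## Walk one alignment record; returns indel evidence and the aligned
## reference span, plus any soft-clip breakpoints for re-anchoring.
walk_alignment <- function(pos, cigar, seq) {
  pc <- parse_cigar(cigar)
  ref <- pos; qi <- 1L
  events <- list(); clips <- list()
  for (k in seq_along(pc$op)) {
    n <- pc$len[k]
    switch(pc$op[k],
      M = { ref <- ref + n; qi <- qi + n },
      I = {
        events[[length(events) + 1L]] <- list(
          type = "INS", anchor = ref - 1L, size = n,
          ins_seq = substr(seq, qi, qi + n - 1L))
        qi <- qi + n
      },
      D = {
        events[[length(events) + 1L]] <- list(
          type = "DEL", anchor = ref - 1L, size = n, ins_seq = "")
        ref <- ref + n
      },
      S = {
        clips[[length(clips) + 1L]] <- list(
          side = if (k == 1L) "left" else "right",
          at = if (k == 1L) pos else ref - 1L,
          seq = substr(seq, qi, qi + n - 1L))
        qi <- qi + n
      })
  }
  list(events = events, clips = clips, span = c(pos, ref - 1L))
}

## Recover a large deletion from a soft-clipped read by exact re-anchoring
## of the clipped sequence against the reference within a window.
reanchor_clip <- function(clip, reference, window) {
  cs <- clip$seq
  if (clip$side == "right") {
    e <- clip$at
    win_s <- e + 2L
    win_e <- min(nchar(reference), e + window)
    if (win_e - win_s + 1L < nchar(cs)) return(NULL)
    hit <- regexpr(cs, substr(reference, win_s, win_e), fixed = TRUE)
    if (hit == -1L) return(NULL)
    q <- win_s + as.integer(hit) - 1L
    size <- q - e - 1L
    if (size <= 0L) return(NULL)
    list(type = "DEL", anchor = e, size = size, ins_seq = "")
  } else {
    p <- clip$at
    win_s <- max(1L, p - window)
    win_e <- p - 2L
    if (win_e - win_s + 1L < nchar(cs)) return(NULL)
    g <- gregexpr(cs, substr(reference, win_s, win_e), fixed = TRUE)[[1]]
    if (g[1] == -1L) return(NULL)
    q <- win_s + as.integer(g[length(g)]) - 1L   # rightmost placement
    anchor <- q + nchar(cs) - 1L
    size <- (p - 1L) - anchor
    if (size <= 0L) return(NULL)
    list(type = "DEL", anchor = anchor, size = size, ins_seq = "")
  }
}

#' Call small indels and deletion breakpoints from gapped alignments
#'
#' Collects insertion/deletion evidence from in-read `I`/`D` operations
#' and from soft-clipped breakpoints (clipped sequences of at least
#' `min_clip_anchor` nt are re-anchored by exact search against the
#' reference within `reanchor_window`, recovering deletions too large for
#' in-read gap representation, such as paralog fusion junctions). Events
#' of the same type within `merge_tolerance` bp and size +/- 1 are merged;
#' the reported position and size are the modal evidence values. Calls
#' with fewer than `min_support` supporting reads are dropped. The
#' phred-like quality is `10 * support`, capped at 250 — a deliberately
#' simple score that is monotone in evidence, so a quality cutoff behaves
#' like a support cutoff.
#'
#' @param alignments SAM-subset data.frame (qname, strand, rname, pos,
#'   cigar, seq), sorted by pos.
#' @param reference Reference chromosome sequence (character).
#' @param min_support Minimum supporting reads (default 3).
#' @param merge_tolerance Positional merge slack in bp (default 3).
#' @param min_clip_anchor Minimum clipped length worth re-anchoring.
#' @param reanchor_window Search window for clip re-anchoring (bp).
#' @return data.frame of calls: chrom, pos (1-based anchored base), ref,
#'   alt, vtype, size, support, spanning, quality, genotype_code (`NA`,
#'   see [assign_genotype()]).
#' @export
call_indels <- function(alignments, reference, min_support = 3L,
                        merge_tolerance = 3L, min_clip_anchor = 15L,
                        reanchor_window = 5000L) {
  if (nrow(alignments) == 0L) return(empty_sv_calls())
  if (is.unsorted(alignments$pos))
    stop("alignments must be sorted by position", call. = FALSE)
  stopifnot(min_support >= 1L)
  events <- list(); spans <- matrix(0L, nrow(alignments), 2L)
  for (i in seq_len(nrow(alignments))) {
    w <- walk_alignment(alignments$pos[i], alignments$cigar[i],
                        alignments$seq[i])
    spans[i, ] <- w$span
    for (ev in w$events) {
      ev$qname <- alignments$qname[i]
      events[[length(events) + 1L]] <- ev
    }
    for (cl in w$clips) {
      if (nchar(cl$seq) < min_clip_anchor) next
      ev <- reanchor_clip(cl, reference, reanchor_window)
      if (!is.null(ev)) {
        ev$qname <- alignments$qname[i]
        events[[length(events) + 1L]] <- ev
      }
    }
  }
  if (!length(events)) return(empty_sv_calls())
  ed <- data.frame(type = vapply(events, `[[`, character(1), "type"),
                   anchor = vapply(events, `[[`, integer(1), "anchor"),
                   size = vapply(events, `[[`, integer(1), "size"),
                   ins_seq = vapply(events, `[[`, character(1), "ins_seq"),
                   qname = vapply(events, `[[`, character(1), "qname"),
                   stringsAsFactors = FALSE)
  chrom <- alignments$rname[1L]
  calls <- list()
  for (ty in unique(ed$type)) {
    sub <- ed[ed$type == ty, , drop = FALSE]
    sub <- sub[order(sub$anchor, sub$size), , drop = FALSE]
    cl_id <- integer(nrow(sub)); cur <- 0L
    for (i in seq_len(nrow(sub))) {
      if (i == 1L || sub$anchor[i] - sub$anchor[i - 1L] > merge_tolerance ||
          abs(sub$size[i] - modal_of(sub$size[cl_id == cur])) > 1L) {
        cur <- cur + 1L
      }
      cl_id[i] <- cur
    }
    for (cid in unique(cl_id)) {
      grp <- sub[cl_id == cid, , drop = FALSE]
      support <- length(unique(grp$qname))
      if (support < min_support) next
      anchor <- modal_of(grp$anchor)
      size <- modal_of(grp$size)
      spanning <- sum(spans[, 1L] <= anchor & spans[, 2L] >= anchor + 1L)
      if (ty == "DEL") {
        ref <- substr(reference, anchor, anchor + size)
        alt <- substr(reference, anchor, anchor)
      } else {
        iseq <- modal_of(grp$ins_seq)
        ref <- substr(reference, anchor, anchor)
        alt <- paste0(ref, iseq)
      }
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = chrom, pos = anchor, ref = ref, alt = alt, vtype = ty,
        size = size, support = support, spanning = spanning,
        quality = min(10 * support, 250),
        genotype_code = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty_sv_calls())
  df <- do.call(rbind, calls)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

modal_of <- function(x) {
  t <- table(x)
  v <- names(t)[which.max(t)]
  if (is.numeric(x)) as.integer(v) else v
}

empty_sv_calls <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), vtype = character(0), size = integer(0),
             support = integer(0), spanning = integer(0),
             quality = numeric(0), genotype_code = character(0),
             stringsAsFactors = FALSE)
}

#' Assign VCF-style genotype codes from allele fractions
#'
#' Per site (calls of any type within `merge_tolerance` bp on one
#' chromosome), alleles are ordered by support. A fraction
#' (support / spanning reads) of at least 0.8 is homozygous, `[0.2, 0.8)`
#' heterozygous, below 0.2 absent. A single alternate allele yields
#' `1/1`, `0/1` or `no_call`; a second distinct allele at the same site
#' yields the multi-allelic codes: both present gives `1/2`, only the
#' second present gives `0/2` (het) or `2/2` (hom). Zero spanning reads
#' yields `no_call`. Hemizygous loci (male X) present all-mutant pileups
#' and therefore genotype as `1/1`.
#'
#' @param calls data.frame from [call_indels()] (needs support, spanning).
#' @param allele_fraction Optional explicit per-call fractions overriding
#'   support/spanning.
#' @param merge_tolerance Site-grouping slack (bp).
#' @return `calls` with `genotype_code` filled.
#' @export
assign_genotype <- function(calls, allele_fraction = NULL,
                            merge_tolerance = 3L) {
  if (!nrow(calls)) return(calls)
  frac <- if (!is.null(allele_fraction)) allele_fraction
          else ifelse(calls$spanning > 0, calls$support / calls$spanning, NA)
  ord <- order(calls$chrom, calls$pos)
  site <- integer(nrow(calls)); cur <- 0L; last_chrom <- ""; last_pos <- -1e9
  for (i in ord) {
    if (calls$chrom[i] != last_chrom ||
        calls$pos[i] - last_pos > merge_tolerance) cur <- cur + 1L
    site[i] <- cur
    last_chrom <- calls$chrom[i]; last_pos <- calls$pos[i]
  }
  gt <- rep("no_call", nrow(calls))
  for (sid in unique(site)) {
    idx <- which(site == sid)   # allele index = order of discovery
    f <- frac[idx]
    present <- !is.na(f) & f >= 0.2
    hom <- !is.na(f) & f >= 0.8
    if (sum(present) >= 2L) {
      # two alternate alleles both present: 1/2 for the first two
      pp <- idx[present][1:2]
      gt[pp] <- "1/2"
    } else {
      for (k in seq_along(idx)) {
        if (!present[k]) next
        code <- if (hom[k]) {
          if (k == 1L) "1/1" else "2/2"
        } else {
          if (k == 1L) "0/1" else "0/2"
        }
        gt[idx[k]] <- code
      }
    }
  }
  calls$genotype_code <- gt
  calls
}

#' Filter calls by quality score
#'
#' Retains calls with `quality >= min_quality`; the survivor count is
#' non-increasing in the cutoff. The default of 100 is the hard
#' high-confidence threshold used for indel screening.
#'
#' @param calls data.frame with a `quality` column.
#' @param min_quality Minimum quality (default 100).
#' @return Filtered data.frame.
#' @export
quality_filter <- function(calls, min_quality = 100) {
  out <- calls[calls$quality >= min_quality, , drop = FALSE]
  rownames(out) <- NULL
  out
}
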