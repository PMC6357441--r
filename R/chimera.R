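#' Infer paralog fusion candidates from PCR amplification patterns
#'
#' A fusion joining the 5' part of gene A to the 3' part of gene B
#' destroys the reverse-primer site of A and the forward-primer site of
#' B, so both gene-specific pairs fail while the mixed pair (A-forward
#' with B-reverse) amplifies the chimeric product. A candidate `A -> B`
#' is therefore emitted iff A's and B's gene-specific pairs both fail
#' and the A-forward/B-reverse mixed pair succeeds. An animal that also
#' amplifies with a gene-specific pair (a mosaic carrying both intact
#' and fused alleles) yields no candidate here.
#'
#' @param amp data.frame with columns `forward_gene`, `reverse_gene`,
#'   `success` (logical), one row per primer pair tested on one animal.
#'   Gene-specific pairs have `forward_gene == reverse_gene`.
#' @return data.frame of candidates: gene_5prime, gene_3prime.
#' @export
infer_chimera_from_amplification <- function(amp) {
  stopifnot(all(c("forward_gene", "reverse_gene", "success") %in% names(amp)))
  specific <- amp[amp$forward_gene == amp$reverse_gene, , drop = FALSE]
  mixed <- amp[amp$forward_gene != amp$reverse_gene & amp$success, ,
               drop = FALSE]
  ok_fail <- function(g) {
    rows <- specific$success[specific$forward_gene == g]
    length(rows) > 0L && !any(rows)
  }
  keep <- vapply(seq_len(nrow(mixed)), function(i)
    ok_fail(mixed$forward_gene[i]) && ok_fail(mixed$reverse_gene[i]),
    logical(1))
  out <- data.frame(gene_5prime = mixed$forward_gene[keep],
                    gene_3prime = mixed$reverse_gene[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build an amplification matrix from simulated X alleles
#'
#' Simulator-side counterpart of [infer_chimera_from_amplification()]:
#' given an individual's per-gene allele lists, a gene-specific pair
#' succeeds iff some allele of that gene is intact enough to retain both
#' primer sites (anything but a fusion), and a mixed A-forward/B-reverse
#' pair succeeds iff a fusion A -> B is carried.
#'
#' @param alleles Named per-gene list of `edit_event` lists (one
#'   haplotype, as from [apply_talen_edits()]).
#' @param genes Gene labels to test (default: all in `alleles`).
#' @return data.frame: forward_gene, reverse_gene, success.
#' @export
amplification_matrix_from_alleles <- function(alleles, genes = names(alleles)) {
  fusion_of <- function(evs) {
    for (ev in evs) {
      if (ev$kind == "fusion") {
        if (!is.null(attr(ev, "fusion_partner_of")))
          return(c(attr(ev, "fusion_partner_of"), ev$partner_gene))
        return(c(ev$gene, ev$partner_gene))
      }
    }
    NULL
  }
  fusions <- list()
  specific_ok <- stats::setNames(rep(FALSE, length(genes)), genes)
  for (g in genes) {
    fu <- fusion_of(alleles[[g]])
    if (is.null(fu)) specific_ok[g] <- TRUE
    else fusions[[length(fusions) + 1L]] <- fu
  }
  rows <- lapply(genes, function(g)
    data.frame(forward_gene = g, reverse_gene = g,
               success = unname(specific_ok[g]), stringsAsFactors = FALSE))
  for (a in genes) for (b in genes) {
    if (a == b) next
    hit <- any(vapply(fusions, function(f) f[1] == a && f[2] == b,
                      logical(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      forward_gene = a, reverse_gene = b, success = hit,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build the sequence of a fusion allele
#'
#' @param seq_a,seq_b Parent gene sequences.
#' @param a Retained 5'-parent prefix length.
#' @param b 1-based start of the retained 3'-parent suffix.
#' @return Fused sequence `A[1..a] + B[b..]`.
#' @export
fuse_sequences <- function(seq_a, seq_b, a, b) {
  paste0(substr(seq_a, 1L, a), substr(seq_b, b, nchar(seq_b)))
}

#' Locate the junction of a paralog fusion amplicon
#'
#' Decomposes an amplicon into a maximal prefix of gene A followed by a
#' maximal suffix of gene B. All valid split points form one contiguous
#' run whose width is exactly the terminal microhomology spanning the
#' junction (bases attributable to either parent); the junction deletion
#' length `len(A) + len(B) - len(amplicon)` is invariant across the run.
#' Among equal decompositions the maximal-microhomology run is inherent
#' in this construction, and coordinates are reported at the leftmost
#' split.
#'
#' @param amplicon Amplicon or read sequence.
#' @param gene_a_seq,gene_b_seq Parent gene sequences (A = 5' partner).
#' @param min_anchor Minimum exact prefix/suffix anchor (nt, default 15).
#' @return List of class `chimera_event`: gene_a_keep (bases of A before
#'   the leftmost junction), gene_b_start (1-based first retained B base
#'   at that split), junction_deletion_len, microhomology_len.
#' @export
locate_fusion_junction <- function(amplicon, gene_a_seq, gene_b_seq,
                                   min_anchor = 15L) {
  la <- nchar(gene_a_seq); lb <- nchar(gene_b_seq); n <- nchar(amplicon)
  p_a <- lcp_len(amplicon, gene_a_seq)
  s_b <- lcs_len(amplicon, gene_b_seq)
  lo <- max(n - s_b, 1L)   # leftmost admissible split
  hi <- min(p_a, n - 1L)   # rightmost admissible split
  if (p_a < min_anchor || s_b < min_anchor || lo > hi)
    stop("no A-prefix/B-suffix decomposition with anchors >= ", min_anchor,
         call. = FALSE)
  structure(list(
    gene_a_keep = lo,
    gene_b_start = lb - (n - lo) + 1L,
    junction_deletion_len = la + lb - n,
    microhomology_len = hi - lo
  ), class = "chimera_event")
}
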