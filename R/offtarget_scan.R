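## 3'-anchored terminal match lengths, in-silico-PCR primer semantics.
##
## For a forward primer, the 3' end is its last base; a placement counts
## the run of consecutive exact matches ending at that base. For the
## plus-strand binding site of a reverse primer the 3' end maps to the
## *first* base of the site, so the run is counted from the left instead.
## Returns an integer vector over all full-length placements (1-based
## start positions); N in the genome never matches.
terminal_match_lengths <- function(genome_chars, primer, from_3prime_right) {
  l <- nchar(primer)
  n <- length(genome_chars)
  np <- n - l + 1L
  if (np < 1L) return(integer(0))
  pch <- strsplit(primer, "", fixed = TRUE)[[1]]
  alive <- rep(TRUE, np)
  run <- integer(np)
  ks <- if (from_3prime_right) l:1 else 1:l
  for (k in ks) {
    alive <- alive & (genome_chars[k:(np + k - 1L)] == pch[k])
    run <- run + alive
  }
  run
}

#' Scan a genome for paired primer-like binding sites
#'
#' Emulates an in-silico PCR search: the left arm sequence acts as the
#' forward primer (plus strand) and the right arm sequence as the reverse
#' primer (matched as its reverse complement on the plus axis, downstream
#' of the left site). A placement qualifies when each primer has a
#' 3'-anchored contiguous exact match of at least `min_perfect_match` nt
#' (mismatches are allowed 5' of that anchor), the sites do not overlap,
#' and the product — measured from the 5' end of the left site to the 5'
#' end of the right primer's site on the plus axis — is at most
#' `max_product` nt. The defaults are the relaxed search settings used to
#' declare an absence of paired off-target sites: a minimum perfect match
#' of 8 nt and a maximum product size of 100 bp.
#'
#' @param genome Character vector of chromosome sequences (ACGTN),
#'   optionally named; unnamed chromosomes are labelled `chr1..`.
#' @param left_seq Forward arm/primer (plus strand, ACGT).
#' @param right_seq Reverse arm/primer (minus strand 5'->3', ACGT).
#' @param min_perfect_match Minimum 3'-anchored exact match (nt),
#'   default 8; must not exceed either primer length.
#' @param max_product Maximum product size (bp), default 100.
#' @return data.frame of hits sorted by (chrom, left_start):
#'   chrom, left_start, left_end, right_start, right_end (0-based
#'   half-open plus-axis coordinates), product_size, left_perfect_match,
#'   right_perfect_match.
#' @export
scan_paired_sites <- function(genome, left_seq, right_seq,
                              min_perfect_match = 8L, max_product = 100L) {
  check_dna(left_seq, what = "left primer")
  check_dna(right_seq, what = "right primer")
  if (min_perfect_match < 1L)
    stop("min_perfect_match must be >= 1", call. = FALSE)
  if (min_perfect_match > min(nchar(left_seq), nchar(right_seq)))
    stop("min_perfect_match exceeds primer length", call. = FALSE)
  if (is.null(names(genome)))
    names(genome) <- paste0("chr", seq_along(genome))
  l <- nchar(left_seq)
  r <- nchar(right_seq)
  right_site <- revcomp(right_seq)
  hits <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    check_dna(seq, allow_n = TRUE, what = paste0("genome (", chrom, ")"))
    gch <- strsplit(seq, "", fixed = TRUE)[[1]]
    tl <- terminal_match_lengths(gch, left_seq, from_3prime_right = TRUE)
    tr <- terminal_match_lengths(gch, right_site, from_3prime_right = FALSE)
    lp <- which(tl >= min_perfect_match)
    rp <- which(tr >= min_perfect_match)
    if (!length(lp) || !length(rp)) next
    rp <- sort(rp)
    for (p in lp) {
      # q in [p + l, p + max_product - r]
      lo <- p + l
      hi <- p + max_product - r
      if (hi < lo) next
      qs <- rp[rp >= lo & rp <= hi]
      for (q in qs) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom,
          left_start = p - 1L, left_end = p - 1L + l,
          right_start = q - 1L, right_end = q - 1L + r,
          product_size = q + r - p,
          left_perfect_match = tl[p],
          right_perfect_match = tr[q],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(0), left_start = integer(0),
                      left_end = integer(0), right_start = integer(0),
                      right_end = integer(0), product_size = integer(0),
                      left_perfect_match = integer(0),
                      right_perfect_match = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, hits)
  df <- df[order(df$chrom, df$left_start, df$right_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Scan a genome for all binding-site orientations of a TALEN pair
#'
#' FokI dimerisation is orientation-symmetric, so a paired site is also
#' scanned with the arms exchanged (the right arm acting as the forward
#' primer). Duplicate placements found by both orientations (palindromic
#' arms) are collapsed.
#'
#' @param genome As in [scan_paired_sites()].
#' @param pair A `talen_pair`.
#' @param min_perfect_match,max_product As in [scan_paired_sites()].
#' @return data.frame of hits with an extra `orientation` column
#'   (`"LR"` or `"RL"`), sorted by (chrom, left_start).
#' @export
scan_for_pair <- function(genome, pair, min_perfect_match = 8L,
                          max_product = 100L) {
  stopifnot(inherits(pair, "talen_pair"))
  a <- scan_paired_sites(genome, pair$left_seq, pair$right_seq,
                         min_perfect_match, max_product)
  b <- scan_paired_sites(genome, pair$right_seq, pair$left_seq,
                         min_perfect_match, max_product)
  if (nrow(a)) a$orientation <- "LR"
  if (nrow(b)) b$orientation <- "RL"
  df <- rbind(if (nrow(a)) a else NULL, if (nrow(b)) b else NULL)
  if (is.null(df) || !nrow(df)) {
    a$orientation <- character(0)
    return(a)
  }
  key <- paste(df$chrom, df$left_start, df$right_start)
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(df$chrom, df$left_start, df$right_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write paired-site hits as BED6
#'
#' One BED record per hit spanning left_start..right_end; the score column
#' carries the smaller of the two perfect-match lengths.
#'
#' @param hits data.frame from [scan_paired_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$chrom, start = hits$left_start,
                    end = hits$right_end,
                    name = paste0("pairhit", seq_len(nrow(hits))),
                    score = pmin(hits$left_perfect_match,
                                 hits$right_perfect_match),
                    strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
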