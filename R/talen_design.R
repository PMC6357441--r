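## The RVD cipher used by TAL effector repeats: one repeat variable
## di-residue per DNA base. NK is an alternative specifier for a T at the
## 3' half repeat only.
RVD_OF_BASE <- c(A = "NI", C = "HD", G = "NN", T = "NG")
BASE_OF_RVD <- c(NI = "A", HD = "C", NN = "G", NG = "T", NK = "T")

#' Encode a DNA recognition sequence as an RVD array
#'
#' Positional cipher: A -> NI, C -> HD, G -> NN, T -> NG. With
#' `nk_for_3prime_T = TRUE` a terminal T is encoded as NK, the alternative
#' specifier sometimes used for the 3' half-repeat position.
#'
#' @param dna Recognition sequence over ACGT (the strand the arm reads).
#' @param nk_for_3prime_T Use NK for a final T?
#' @return Character vector of RVDs, class `rvd_array`.
#' @export
#' @examples
#' encode_rvd("ACGT")
#' encode_rvd("ACGT", nk_for_3prime_T = TRUE)
encode_rvd <- function(dna, nk_for_3prime_T = FALSE) {
  stopifnot(is.character(dna), length(dna) == 1L)
  if (!nzchar(dna)) stop("empty recognition sequence", call. = FALSE)
  bases <- strsplit(dna, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(bases), names(RVD_OF_BASE))
  if (length(bad))
    stop("cannot encode ambiguous base(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  rvds <- unname(RVD_OF_BASE[bases])
  if (nk_for_3prime_T && bases[length(bases)] == "T")
    rvds[length(rvds)] <- "NK"
  structure(rvds, class = "rvd_array")
}

#' Decode an RVD array back to DNA
#'
#' Inverse of [encode_rvd()]; NK decodes to T and is only legal at the
#' final (3' half-repeat) position.
#'
#' @param rvds Character vector of RVDs over NI/HD/NN/NG/NK.
#' @return DNA string.
#' @export
#' @examples
#' decode_rvd(c("NI", "HD", "NN", "NG"))
decode_rvd <- function(rvds) {
  rvds <- unclass(rvds)
  if (length(rvds) == 0L) stop("empty RVD array", call. = FALSE)
  bad <- setdiff(unique(rvds), names(BASE_OF_RVD))
  if (length(bad))
    stop("unknown RVD(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if ("NK" %in% rvds[-length(rvds)])
    stop("NK is only valid at the final (3' half-repeat) position",
         call. = FALSE)
  paste(BASE_OF_RVD[rvds], collapse = "")
}

#' Construct a TALEN pair
#'
#' The left arm reads the plus strand 5'->3'; the right arm reads the
#' minus strand 5'->3' (so its binding site on the plus strand is the
#' reverse complement of `right_seq`). The spacer is the run of bases
#' strictly between the two binding sites on the plus strand; the FokI
#' domains only cleave when both arms bind across such a spacer.
#'
#' @param left_seq,right_seq Recognition sequences (each read 5'->3' on
#'   its own strand), equal length.
#' @param spacer_min,spacer_max Admissible spacer length (nt).
#' @param nk_for_3prime_T Passed to [encode_rvd()].
#' @return A list of class `talen_pair` with arms, RVD arrays and spacer
#'   constraints.
#' @export
talen_pair <- function(left_seq, right_seq, spacer_min = 12L,
                       spacer_max = 20L, nk_for_3prime_T = TRUE) {
  check_dna(left_seq, what = "left arm")
  check_dna(right_seq, what = "right arm")
  if (nchar(left_seq) != nchar(right_seq))
    stop("arm lengths differ", call. = FALSE)
  if (spacer_min > spacer_max)
    stop("spacer_min > spacer_max", call. = FALSE)
  structure(list(
    left_seq = left_seq,
    right_seq = right_seq,
    left_rvd = encode_rvd(left_seq, nk_for_3prime_T),
    right_rvd = encode_rvd(right_seq, nk_for_3prime_T),
    arm_len = nchar(left_seq),
    spacer_min = as.integer(spacer_min),
    spacer_max = as.integer(spacer_max)
  ), class = "talen_pair")
}

#' @export
print.talen_pair <- function(x, ...) {
  cat("TALEN pair (arm", x$arm_len, "nt, spacer",
      paste0(x$spacer_min, "-", x$spacer_max), "nt)\n")
  cat("  left  (+): ", x$left_seq, "  ", paste(x$left_rvd, collapse = " "),
      "\n", sep = "")
  cat("  right (-): ", x$right_seq, "  ", paste(x$right_rvd, collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Enumerate candidate TALEN pairs within the gene copies of a family
#'
#' Every returned pair has its left arm on the plus strand, its right arm
#' on the minus strand, a spacer within `spacer_range`, and both binding
#' sites fully inside a single gene copy. With `require_5prime_T` the base
#' immediately 5' of each arm (on the arm's own strand) must be T, the
#' usual TAL-effector context convention.
#'
#' @param family A `paralog_family`.
#' @param arm_len Recognition arm length (>= 8; default 15).
#' @param spacer_range Length-2 integer vector (min, max) spacer.
#' @param require_5prime_T Enforce the 5'-T context base?
#' @param genes Optional subset of gene labels to search (default: all
#'   copies including the pseudogene).
#' @return data.frame with one row per pair: gene, left_start (0-based,
#'   chromosome coords), spacer, left_seq, right_seq, left_rvd, right_rvd;
#'   sorted by position, then spacer, then arm sequence.
#' @export
enumerate_pairs <- function(family, arm_len = 15L,
                            spacer_range = c(12L, 20L),
                            require_5prime_T = TRUE, genes = NULL) {
  stopifnot(arm_len >= 8L)
  if (spacer_range[1] > spacer_range[2])
    stop("inverted spacer_range", call. = FALSE)
  if (is.null(genes)) genes <- family$copies$gene
  out <- list()
  for (g in genes) {
    copy <- family_copy_seq(family, g)
    gstart <- family$copies$start[family$copies$gene == g]
    L <- nchar(copy)
    ch <- strsplit(copy, "", fixed = TRUE)[[1]]
    for (i in seq_len(max(0L, L - 2L * arm_len - spacer_range[1] + 1L))) {
      left_site <- substr(copy, i, i + arm_len - 1L)
      if (require_5prime_T && (i == 1L || ch[i - 1L] != "T")) next
      for (s in spacer_range[1]:spacer_range[2]) {
        j <- i + arm_len + s          # right site start (1-based in copy)
        if (j + arm_len - 1L > L) break
        # right arm's 5' context base on the minus strand is the
        # complement of the plus base just 3' of the site
        if (require_5prime_T &&
            (j + arm_len > L || ch[j + arm_len] != "A")) next
        right_site <- substr(copy, j, j + arm_len - 1L)
        out[[length(out) + 1L]] <- data.frame(
          gene = g,
          left_start = gstart + i - 1L,   # 0-based chromosome coordinate
          spacer = s,
          left_seq = left_site,
          right_seq = revcomp(right_site),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), left_start = integer(0),
                      spacer = integer(0), left_seq = character(0),
                      right_seq = character(0), left_rvd = character(0),
                      right_rvd = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$left_start, df$spacer, df$left_seq), , drop = FALSE]
  df$left_rvd <- vapply(df$left_seq,
                        function(s) paste(encode_rvd(s), collapse = "-"),
                        character(1), USE.NAMES = FALSE)
  df$right_rvd <- vapply(df$right_seq,
                         function(s) paste(encode_rvd(s), collapse = "-"),
                         character(1), USE.NAMES = FALSE)
  rownames(df) <- NULL
  df
}

## Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Classify the paralog specificity of a TALEN pair
#'
#' A gene copy is *hit* when some placement within it matches the left arm
#' on the plus strand and the right arm on the minus strand, each within
#' `max_mismatch_per_arm` Hamming mismatches, separated by a spacer within
#' the pair's constraint. The class summarises the hit pattern over the
#' functional copies: `family_wide` (all functional copies hit),
#' `single_copy` (exactly one), `partial` (some but not all), or `none`.
#' The pseudogene is reported but excluded from the class.
#'
#' @param pair A `talen_pair`.
#' @param family A `paralog_family`.
#' @param max_mismatch_per_arm Maximum Hamming mismatches tolerated per
#'   arm (no indels: TAL repeats read contiguous bases).
#' @return List of class `specificity_report`: `per_copy` data.frame
#'   (gene, hit, left_mismatch, right_mismatch — minimum over placements),
#'   and `class`.
#' @export
classify_specificity <- function(pair, family, max_mismatch_per_arm = 0L) {
  stopifnot(inherits(pair, "talen_pair"), max_mismatch_per_arm >= 0L)
  right_site <- revcomp(pair$right_seq)  # plus-strand binding site
  al <- pair$arm_len
  rows <- lapply(family$copies$gene, function(g) {
    copy <- family_copy_seq(family, g)
    L <- nchar(copy)
    best <- c(left = NA_integer_, right = NA_integer_)
    hit <- FALSE
    imax <- L - 2L * al - pair$spacer_min + 1L
    if (imax >= 1L) for (i in seq_len(imax)) {
      dl <- hamming(substr(copy, i, i + al - 1L), pair$left_seq)
      if (dl > max_mismatch_per_arm) next
      for (s in pair$spacer_min:pair$spacer_max) {
        j <- i + al + s
        if (j + al - 1L > L) break
        dr <- hamming(substr(copy, j, j + al - 1L), right_site)
        if (dr <= max_mismatch_per_arm) {
          hit <- TRUE
          if (is.na(best["left"]) || dl + dr < sum(best)) {
            best <- c(left = dl, right = dr)
          }
        }
      }
    }
    data.frame(gene = g, hit = hit,
               left_mismatch = unname(best["left"]),
               right_mismatch = unname(best["right"]),
               stringsAsFactors = FALSE)
  })
  per_copy <- do.call(rbind, rows)
  fun <- functional_copies(family)
  nhit <- sum(per_copy$hit[per_copy$gene %in% fun])
  cls <- if (nhit == length(fun)) "family_wide"
         else if (nhit == 1L) "single_copy"
         else if (nhit == 0L) "none"
         else "partial"
  structure(list(per_copy = per_copy, class = cls),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("Specificity class:", x$class, "\n")
  print(x$per_copy)
  invisible(x)
}
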