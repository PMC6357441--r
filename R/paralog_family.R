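#' Simulate a multi-copy paralog family on a toy chromosome
#'
#' Builds a single chromosome carrying `n_copies` homologous gene copies
#' (plus, optionally, a more diverged pseudogene), embedded in random
#' flanking sequence. Copies are derived from one ancestral sequence by
#' substituting at most `floor((1 - min_identity) * copy_len / 2)`
#' positions per copy, which guarantees every pairwise identity between
#' functional copies is at least `min_identity`. This mirrors an X-linked
#' histone-variant family of three gene copies that are more than 92%
#' identical to each other plus one pseudogene.
#'
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param n_copies Number of functional gene copies (>= 1).
#' @param copy_len Length of each copy in nt (>= 60).
#' @param min_identity Minimum pairwise identity between functional
#'   copies, in (0, 1]. Default 0.92.
#' @param flank_len Random flank length placed before, between and after
#'   copies.
#' @param with_pseudogene Add one diverged (~85% identity) pseudogene copy?
#' @param copy_labels Optional character vector of gene labels, length
#'   `n_copies`.
#' @param divergence_sites Optional explicit per-copy substitution count;
#'   incompatible with `min_identity = 1` when positive.
#' @return An object of class `paralog_family`: a list with
#'   `chromosome_name`, `sequence`, `copies` (data.frame: gene, start,
#'   end, strand; 0-based half-open), `pseudogene` (label or `NA`) and
#'   `identity_matrix` (pairwise identity of functional copies).
#' @export
#' @examples
#' fam <- make_paralog_family(1, n_copies = 3, copy_len = 300)
#' fam$identity_matrix
make_paralog_family <- function(seed, n_copies = 3L, copy_len = 500L,
                                min_identity = 0.92, flank_len = 500L,
                                with_pseudogene = TRUE,
                                copy_labels = NULL,
                                divergence_sites = NULL) {
  stopifnot(n_copies >= 1L, copy_len >= 60L,
            min_identity > 0, min_identity <= 1, flank_len >= 0L)
  d <- if (is.null(divergence_sites))
    floor((1 - min_identity) * copy_len / 2) else as.integer(divergence_sites)
  if (min_identity == 1 && d > 0L)
    stop("min_identity = 1 contradicts a positive number of divergence sites",
         call. = FALSE)
  if (is.null(copy_labels)) copy_labels <- paste0("gene", seq_len(n_copies))
  stopifnot(length(copy_labels) == n_copies, !anyDuplicated(copy_labels))

  with_seed(derive_seed(seed, "family"), {
    ancestor <- random_dna(copy_len)
    seqs <- vapply(seq_len(n_copies), function(i) mutate_positions(ancestor, d),
                   character(1))
    labels <- copy_labels
    if (with_pseudogene) {
      # a pseudogene diverges well past the family floor (~85% identity)
      ps <- mutate_positions(ancestor, floor(0.15 * copy_len))
      seqs <- c(seqs, ps)
      labels <- c(labels, "pseudo")
    }
    n_all <- length(seqs)
    flanks <- vapply(seq_len(n_all + 1L), function(i) random_dna(flank_len),
                     character(1))
    pieces <- character(0)
    start <- integer(n_all)
    for (i in seq_len(n_all)) {
      pieces <- c(pieces, flanks[i])
      start[i] <- sum(nchar(pieces))
      pieces <- c(pieces, seqs[i])
    }
    pieces <- c(pieces, flanks[n_all + 1L])
    sequence <- paste(pieces, collapse = "")

    idm <- diag(1, n_copies)
    dimnames(idm) <- list(copy_labels, copy_labels)
    if (n_copies >= 2L) {
      for (i in seq_len(n_copies - 1L)) for (j in (i + 1L):n_copies) {
        idm[i, j] <- idm[j, i] <- seq_identity(seqs[i], seqs[j])
      }
    }
    structure(list(
      chromosome_name = "chrX_sim",
      sequence = sequence,
      copies = data.frame(gene = labels, start = start,
                          end = start + copy_len, strand = "+",
                          stringsAsFactors = FALSE),
      pseudogene = if (with_pseudogene) "pseudo" else NA_character_,
      copy_len = copy_len,
      min_identity = min_identity,
      identity_matrix = idm
    ), class = "paralog_family")
  })
}

#' @export
print.paralog_family <- function(x, ...) {
  cat("Paralog family on", x$chromosome_name,
      sprintf("(%d nt)\n", nchar(x$sequence)))
  print(x$copies)
  if (nrow(x$identity_matrix) > 1L)
    cat("min pairwise identity:",
        format(min(x$identity_matrix[upper.tri(x$identity_matrix)]),
               digits = 4), "\n")
  invisible(x)
}

#' Labels of the functional (non-pseudogene) copies
#' @param family A `paralog_family`.
#' @return Character vector of gene labels.
#' @export
functional_copies <- function(family) {
  setdiff(family$copies$gene, family$pseudogene)
}

#' Extract the sequence of one gene copy
#' @param family A `paralog_family`.
#' @param gene Gene label.
#' @return The copy sequence (character).
#' @export
family_copy_seq <- function(family, gene) {
  row <- family$copies[family$copies$gene == gene, ]
  if (nrow(row) != 1L) stop("unknown gene label: ", gene, call. = FALSE)
  substr(family$sequence, row$start + 1L, row$end)
}

#' Write a family chromosome as FASTA (60-column wrap)
#' @param family A `paralog_family`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_family_fasta <- function(family, path) {
  ss <- Biostrings::DNAStringSet(family$sequence)
  names(ss) <- family$chromosome_name
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
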