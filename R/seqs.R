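DNA_BASES <- c("A", "C", "G", "T")

#' Generate a random DNA string
#' @param len Length in nucleotides.
#' @return A single character string over ACGT.
#' @keywords internal
random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

#' Reverse-complement a DNA string
#' @param x Character vector of DNA strings (ACGTN).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

## Substitute `n` positions of `seq` with a different base each.
mutate_positions <- function(seq, n) {
  if (n == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

## Fraction of identical positions between two equal-length strings.
seq_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}

## Longest common prefix / suffix lengths of two strings.
lcp_len <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- min(length(ca), length(cb))
  if (n == 0L) return(0L)
  neq <- which(ca[seq_len(n)] != cb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

lcs_len <- function(a, b) {
  ca <- rev(strsplit(a, "", fixed = TRUE)[[1]])
  cb <- rev(strsplit(b, "", fixed = TRUE)[[1]])
  n <- min(length(ca), length(cb))
  if (n == 0L) return(0L)
  neq <- which(ca[seq_len(n)] != cb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

## Check a DNA alphabet; N allowed only when `allow_n`.
check_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, x))
    stop(what, " contains characters outside ",
         if (allow_n) "ACGTN" else "ACGT", call. = FALSE)
  invisible(x)
}
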