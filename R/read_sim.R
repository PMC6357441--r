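## CIGAR assembly for one read sampled from an edited haplotype.
## `blocks` maps haplotype M segments to reference coordinates; the gap
## between consecutive blocks is a deletion (ref jumps) and/or an
## insertion (hap positions outside every block). Deletions larger than
## `max_del_in_cigar` truncate the alignment: the portion of the read on
## the far side of the jump is soft-clipped, mimicking how short-read
## aligners represent breakpoints that exceed the gap model.
read_alignment <- function(blocks, s, e, max_del_in_cigar) {
  ops <- character(0)
  lens <- integer(0)
  push <- function(op, n) {
    if (n <= 0L) return()
    k <- length(ops)
    if (k > 0L && ops[k] == op) lens[k] <<- lens[k] + n
    else { ops[k + 1L] <<- op; lens[k + 1L] <<- n }
  }
  pos <- NA_integer_   # reference position of first aligned base
  ref_end <- NA_integer_
  cur <- s
  clipped_rest <- FALSE
  for (bi in seq_len(nrow(blocks))) {
    b_hs <- blocks$hap_start[bi]
    b_he <- b_hs + blocks$len[bi] - 1L
    if (b_he < cur) next
    if (cur > e) break
    if (b_hs > cur) {
      # haplotype positions before this block are inserted sequence
      ins_end <- min(b_hs - 1L, e)
      n_ins <- ins_end - cur + 1L
      if (is.na(pos)) push("S", n_ins) else push("I", n_ins)
      cur <- ins_end + 1L
      if (cur > e) break
    }
    # deletion between previous block and this one
    if (!is.na(ref_end)) {
      d <- blocks$ref_start[bi] - ref_end - 1L
      if (d > 0L) {
        if (d > max_del_in_cigar) {
          push("S", e - cur + 1L)
          clipped_rest <- TRUE
          break
        }
        push("D", d)
      }
    }
    m_end <- min(b_he, e)
    n_m <- m_end - cur + 1L
    if (is.na(pos)) pos <- blocks$ref_start[bi] + (cur - b_hs)
    push("M", n_m)
    ref_end <- blocks$ref_start[bi] + (m_end - b_hs)
    cur <- m_end + 1L
  }
  if (!clipped_rest && cur <= e) {
    # read runs off the last block into inserted/terminal sequence
    if (is.na(pos)) push("S", e - cur + 1L) else push("S", e - cur + 1L)
  }
  # drop trailing D (alignment cannot end in a deletion)
  while (length(ops) && ops[length(ops)] == "D") {
    ref_end <- ref_end  # deletion consumed no read bases
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  while (length(ops) && ops[1L] == "D") { ops <- ops[-1L]; lens <- lens[-1L] }
  list(pos = pos, cigar = if (length(ops))
    paste0(lens, ops, collapse = "") else "*")
}

#' Simulate gapped short-read alignments from an edited haplotype
#'
#' Draws uniformly placed single-end reads from the edited haplotype and
#' reports each one with the gapped alignment (CIGAR M/I/D/S operations)
#' it would have against the *unedited* reference, computed exactly from
#' the known edit map: engineered deletions appear as `D` operations, or
#' as soft-clipped reads when they exceed `max_del_in_cigar`;
#' insertions appear as `I`/`S`. Substitution errors are applied at
#' `base_error_rate`. Deterministic for a fixed seed and stream.
#'
#' @param genome_with_edits An `edited_haplotype` from
#'   [apply_edits_to_sequence()].
#' @param params A [sim_params()] bundle (`read_len`, `coverage`,
#'   `base_error_rate`, `max_del_in_cigar`).
#' @param rname Reference sequence name for the records.
#' @param stream RNG stream tag (vary per sample).
#' @return data.frame (SAM-subset): qname, strand, rname, pos (1-based),
#'   cigar, seq; sorted by pos.
#' @export
simulate_reads <- function(genome_with_edits, params, rname = "chrX_sim",
                           stream = "reads") {
  stopifnot(inherits(genome_with_edits, "edited_haplotype"))
  hap <- genome_with_edits$haplotype
  blocks <- genome_with_edits$blocks
  L <- nchar(hap)
  rl <- params$read_len
  if (rl <= 0L) stop("read_len must be positive", call. = FALSE)
  if (rl >= L) stop("read_len must be shorter than the haplotype",
                    call. = FALSE)
  n_reads <- max(1L, round(params$coverage * L / rl))
  with_seed(derive_seed(params$seed, stream), {
    starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
    recs <- lapply(seq_len(n_reads), function(i) {
      s <- starts[i]; e <- s + rl - 1L
      aln <- read_alignment(blocks, s, e, params$max_del_in_cigar)
      seq <- substr(hap, s, e)
      if (params$base_error_rate > 0) {
        ch <- strsplit(seq, "", fixed = TRUE)[[1]]
        err <- which(stats::runif(rl) < params$base_error_rate)
        for (p in err) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
        seq <- paste(ch, collapse = "")
      }
      data.frame(qname = sprintf("read%06d", i), strand = "+",
                 rname = rname,
                 pos = if (is.na(aln$pos)) 0L else aln$pos,
                 cigar = aln$cigar, seq = seq, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, recs)
    df <- df[df$pos > 0L & df$cigar != "*", , drop = FALSE]  # unplaceable reads
    df <- df[order(df$pos), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

#' Write/read the SAM-subset TSV interchange format
#'
#' Columns: qname, strand, rname, pos, cigar, seq.
#'
#' @param alignments data.frame from [simulate_reads()].
#' @param path File path.
#' @return `path` (writer) or the data.frame (reader).
#' @export
write_sam_tsv <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sam_tsv
#' @export
read_sam_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "character",
                                   "integer", "character", "character"),
                    stringsAsFactors = FALSE)
}
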