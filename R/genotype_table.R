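## The founder-genotype notation used in colony screening tables:
##   "XX (wt)" / "XY (wt)"            wild type (female / male)
##   "X^<spec>^ X^<spec>^"            female, two alleles
##   "X^<spec>^ Y"                    male, one allele
##   <spec>: "∆5" (deletion of 5 nt), "+286" (insertion),
##           "∆5+286" (delins), or a substitution tag ("C/T, A/G")
##   "No successful PCR amplification"  locus not amplifiable
##   trailing "Chimera ..." annotations are kept verbatim as tags
## Both Greek Delta (U+0394) and the increment sign (U+2206) are accepted.

normalize_delta <- function(x) gsub("Δ", "∆", x)

parse_allele_spec <- function(spec) {
  spec <- trimws(spec)
  d <- "∆"
  if (grepl(paste0("^", d, "\\s*[0-9]+\\s*\\+\\s*[0-9]+$"), spec)) {
    nums <- as.integer(regmatches(spec, gregexpr("[0-9]+", spec))[[1]])
    list(kind = "delins", del_len = nums[1], ins_len = nums[2], tag = spec)
  } else if (grepl(paste0("^", d, "\\s*[0-9]+$"), spec)) {
    n <- as.integer(regmatches(spec, regexpr("[0-9]+", spec)))
    if (n < 1L) stop("malformed allele token: ", spec, call. = FALSE)
    list(kind = "del", del_len = n, ins_len = 0L, tag = spec)
  } else if (grepl("^\\+\\s*[0-9]+$", spec)) {
    n <- as.integer(regmatches(spec, regexpr("[0-9]+", spec)))
    list(kind = "ins", del_len = 0L, ins_len = n, tag = spec)
  } else if (grepl("^[ACGT]/[ACGT]", spec)) {
    list(kind = "subst", del_len = 0L, ins_len = 0L, tag = spec)
  } else {
    stop("malformed allele token: '", spec, "'", call. = FALSE)
  }
}

#' Parse one gene's genotype cell in colony-table notation
#'
#' @param text Genotype cell, e.g. `"XX (wt)"`, `"X^∆5+286^ Y"`,
#'   `"X^∆22^ X^∆160^"`, `"No successful PCR amplification"`.
#' @param sex `"male"` or `"female"` (allele-count validation).
#' @return List of class `genotype_record`: `alleles` (list of
#'   descriptors with kind/del_len/ins_len/tag), `failed_amplification`,
#'   `chimera_tag` (verbatim annotation or `NA`).
#' @export
#' @examples
#' parse_genotype("X^∆5+286^ Y", "male")
#' parse_genotype("XX (wt)", "female")
parse_genotype <- function(text, sex) {
  sex <- match.arg(sex, c("male", "female"))
  text <- normalize_delta(trimws(text))
  chimera_tag <- NA_character_
  cm <- regexpr("Chimera.*$", text)
  if (cm != -1L) {
    chimera_tag <- trimws(regmatches(text, cm))
    text <- trimws(sub("Chimera.*$", "", text))
  }
  rec <- function(alleles, failed = FALSE)
    structure(list(alleles = alleles, failed_amplification = failed,
                   chimera_tag = chimera_tag, sex = sex),
              class = "genotype_record")
  if (grepl("^No successful PCR amplification\\.?$", text))
    return(rec(list(), failed = TRUE))
  n_expected <- if (sex == "male") 1L else 2L
  if (grepl("^X{1,2}Y?\\s*\\(wt\\)$", text)) {
    wt <- list(kind = "wt", del_len = 0L, ins_len = 0L, tag = "wt")
    return(rec(rep(list(wt), n_expected)))
  }
  toks <- regmatches(text, gregexpr("X\\^[^^]*\\^|\\bY\\b", text))[[1]]
  leftover <- trimws(gsub("X\\^[^^]*\\^|\\bY\\b", "", text))
  if (nzchar(leftover))
    stop("malformed genotype token: '", leftover, "'", call. = FALSE)
  x_toks <- toks[startsWith(toks, "X^")]
  has_y <- any(toks == "Y")
  if (sex == "male" && (!has_y || length(x_toks) != 1L))
    stop("male genotype must be one X allele plus Y: '", text, "'",
         call. = FALSE)
  if (sex == "female" && (has_y || length(x_toks) != 2L))
    stop("female genotype must be two X alleles: '", text, "'",
         call. = FALSE)
  alleles <- lapply(x_toks, function(t)
    parse_allele_spec(sub("^X\\^", "", sub("\\^$", "", t))))
  rec(alleles)
}

#' Format a genotype record back to table notation
#'
#' Inverse of [parse_genotype()] on the canonical dialect, so
#' `parse(format(parse(x)))` equals `parse(x)`.
#'
#' @param record A `genotype_record`.
#' @return Character genotype cell.
#' @export
format_genotype <- function(record) {
  stopifnot(inherits(record, "genotype_record"))
  tag <- if (!is.na(record$chimera_tag)) paste0(" ", record$chimera_tag) else ""
  if (record$failed_amplification)
    return(paste0("No successful PCR amplification", tag))
  kinds <- vapply(record$alleles, `[[`, character(1), "kind")
  if (all(kinds == "wt")) {
    core <- if (record$sex == "male") "XY (wt)" else "XX (wt)"
    return(paste0(core, tag))
  }
  spec <- vapply(record$alleles, function(a) paste0("X^", a$tag, "^"),
                 character(1))
  core <- if (record$sex == "male") paste(spec, "Y") else
    paste(spec, collapse = " ")
  paste0(core, tag)
}

#' Read a founder genotype table (TSV)
#'
#' Expects columns `pup_id`, `sex`, then one column per gene in table
#' notation. The packaged fixture `founder_genotypes.tsv` transcribes a
#' 19-pup founder screen over three X-linked paralogs.
#'
#' @param path TSV path.
#' @return List of per-pup records: `pup_id`, `sex`, `genes` (named list
#'   of `genotype_record`s).
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  genes <- setdiff(names(df), c("pup_id", "sex"))
  lapply(seq_len(nrow(df)), function(i) {
    sex <- df$sex[i]
    list(pup_id = df$pup_id[i], sex = sex,
         genes = stats::setNames(
           lapply(genes, function(g) parse_genotype(df[[g]][i], sex)),
           genes))
  })
}

#' Summarise founder outcomes across a gene family
#'
#' A pup counts as modified-in-all-genes when every gene with an
#' informative result carries at least one non-wild-type allele. With the
#' default `failed_amp_policy = "modified"`, a locus that fails to
#' amplify counts as informative-and-modified, because paralog fusions
#' destroy gene-specific primer sites; under `"missing"` such loci are
#' excluded from the judgement. An all-or-nothing editing outcome shows
#' up as `n_partial = 0`.
#'
#' @param records List of pup records from [read_genotype_table()].
#' @param failed_amp_policy `"modified"` (default) or `"missing"`.
#' @return List: n_total, n_modified_all_genes, n_unmodified, n_partial,
#'   n_with_failed_amp.
#' @export
founder_summary <- function(records,
                            failed_amp_policy = c("modified", "missing")) {
  failed_amp_policy <- match.arg(failed_amp_policy)
  if (!length(records)) stop("empty genotype table", call. = FALSE)
  n_mod <- n_unmod <- n_part <- n_failed <- 0L
  for (r in records) {
    status <- vapply(r$genes, function(g) {
      if (g$failed_amplification) {
        if (failed_amp_policy == "modified") "modified" else "missing"
      } else if (all(vapply(g$alleles, `[[`, character(1), "kind") == "wt")) {
        "wt"
      } else "modified"
    }, character(1))
    if (any(vapply(r$genes, `[[`, logical(1), "failed_amplification")))
      n_failed <- n_failed + 1L
    informative <- status[status != "missing"]
    if (!length(informative)) { n_part <- n_part + 1L; next }
    if (all(informative == "modified")) n_mod <- n_mod + 1L
    else if (all(informative == "wt")) n_unmod <- n_unmod + 1L
    else n_part <- n_part + 1L
  }
  list(n_total = length(records), n_modified_all_genes = n_mod,
       n_unmodified = n_unmod, n_partial = n_part,
       n_with_failed_amp = n_failed)
}
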