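# Shared fixture builders and independent oracles. Oracles are written
# as plainly as possible (scalar loops, direct string comparison) and
# never share code with the implementation paths they check.

rand_genome <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rc_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# A family whose three copies carry one identical planted TALEN site
# (left site + spacer + right site), so specificity/on-target behaviour
# is fully known.
planted_family <- function(seed = 1, spacer = 14, arm_len = 15) {
  set.seed(seed)
  left_site <- rand_genome(arm_len)
  spc <- rand_genome(spacer)
  right_site <- rand_genome(arm_len)
  site <- paste0(left_site, spc, right_site)
  fam <- make_paralog_family(seed, n_copies = 3, copy_len = 400,
                             flank_len = 300)
  # overwrite the centre of each copy with the identical site
  seq <- fam$sequence
  for (i in seq_len(nrow(fam$copies))) {
    if (fam$copies$gene[i] == fam$pseudogene) next
    at <- fam$copies$start[i] + 150
    substr(seq, at + 1, at + nchar(site)) <- site
  }
  fam$sequence <- seq
  list(family = fam, left_seq = left_site, right_seq = rc_chr(right_site),
       spacer = spacer, site = site)
}

# Scalar-loop oracle for the paired in-silico-PCR scan. Terminal runs are
# measured with character-by-character substr comparison; pairing is an
# explicit double loop.
oracle_terminal_runs <- function(seq, primer, from_right) {
  l <- nchar(primer)
  n <- nchar(seq)
  np <- n - l + 1
  if (np < 1) return(integer(0))
  out <- integer(np)
  for (p in seq_len(np)) {
    t <- 0
    while (t < l) {
      k <- if (from_right) l - t else t + 1
      if (substr(seq, p + k - 1, p + k - 1) != substr(primer, k, k)) break
      t <- t + 1
    }
    out[p] <- t
  }
  out
}

oracle_pair_scan <- function(seq, left, right, min_pm, max_prod,
                             runs_l = NULL, runs_r = NULL) {
  l <- nchar(left); r <- nchar(right)
  if (is.null(runs_l)) runs_l <- oracle_terminal_runs(seq, left, TRUE)
  if (is.null(runs_r)) runs_r <- oracle_terminal_runs(seq, rc_chr(right), FALSE)
  lp <- which(runs_l >= min_pm)
  rp <- which(runs_r >= min_pm)
  hits <- list()
  for (p in lp) for (q in rp) {
    if (q >= p + l && q + r - p <= max_prod) {
      hits[[length(hits) + 1]] <- c(left_start = p - 1, right_start = q - 1,
                                    product = q + r - p)
    }
  }
  if (!length(hits)) {
    return(data.frame(left_start = integer(0), right_start = integer(0),
                      product = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, hits))
  df[order(df$left_start, df$right_start), , drop = FALSE]
}

# Brute-force specificity oracle: try every offset and spacer directly.
oracle_copy_hit <- function(copy, left_seq, right_site, smin, smax, max_mm) {
  al <- nchar(left_seq)
  L <- nchar(copy)
  mm <- function(a, b) {
    d <- 0
    for (k in seq_len(nchar(a)))
      if (substr(a, k, k) != substr(b, k, k)) d <- d + 1
    d
  }
  for (i in seq_len(max(0, L - 2 * al - smin + 1))) {
    if (mm(substr(copy, i, i + al - 1), left_seq) > max_mm) next
    for (s in smin:smax) {
      j <- i + al + s
      if (j + al - 1 > L) break
      if (mm(substr(copy, j, j + al - 1), right_site) <= max_mm) return(TRUE)
    }
  }
  FALSE
}

# Exhaustive decomposition oracle for fusion junctions: test every split
# point by direct string equality.
oracle_junction <- function(amplicon, A, B, min_anchor) {
  n <- nchar(amplicon)
  splits <- c()
  for (s in seq_len(n - 1)) {
    if (s < min_anchor || n - s < min_anchor) next
    if (substr(amplicon, 1, s) == substr(A, 1, s) &&
        substr(amplicon, s + 1, n) ==
          substr(B, nchar(B) - (n - s) + 1, nchar(B))) {
      splits <- c(splits, s)
    }
  }
  if (!length(splits)) return(NULL)
  list(splits = splits, mh = max(splits) - min(splits),
       del = nchar(A) + nchar(B) - n)
}
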