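#' Derive a labelled child seed from a top-level seed
#'
#' All randomness in the package flows from one user-supplied integer seed.
#' Each simulation stage draws from its own labelled stream, derived
#' deterministically from the top-level seed, so adding one stage (or
#' changing its internal draw count) does not perturb the others.
#'
#' @param seed Integer top-level seed.
#' @param label Character stream label, e.g. `"family"`, `"pedigree"`.
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "family")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed),
            is.character(label), length(label) == 1L, nzchar(label))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% m
  s <- abs(as.numeric(seed)) %% m
  # two multiplicative mixes; operands stay < 2^53 so doubles are exact
  x <- (s * 48271 + h) %% m
  x <- (x * 69621 + 1) %% m
  as.integer(x + 1)
}

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed`, so simulation helpers never disturb
#' the caller's RNG stream.
#'
#' @param seed Integer seed passed to [set.seed()].
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
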