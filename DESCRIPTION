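Package: talenko
Title: TALEN Design and Pedigree-Based Off-Target Verification for
    Multi-Copy Gene Knockouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing transcription activator-like effector
    nuclease (TALEN) pairs against highly similar paralogous gene
    families, scanning genomes for paired off-target binding sites with
    in-silico-PCR semantics, calling small indels and structural
    variants from gapped alignments, and classifying candidate
    off-target variants by their Mendelian dilution pattern across
    backcross generations. Ships a fully seeded synthetic-data module
    that simulates X-linked paralog families, nuclease-induced indels
    and paralog fusion alleles with junction microhomology, backcross
    pedigrees, strain background variants, noisy variant calls and
    gapped short-read alignments, so the whole design-edit-verify
    workflow can be exercised end to end against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
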