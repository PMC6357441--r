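---
title: "Designing and verifying multi-copy TALEN knockouts: methods"
author: "talenko authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and verifying multi-copy TALEN knockouts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(talenko)
```

## The problem

Some genes exist as families of near-identical paralogs. Knocking such a
family out with a programmable nuclease poses two linked computational
problems. First, *design*: a TALEN pair can be aimed either at one copy
(exploiting the few bases that differ) or at every copy at once
(confining both binding arms to conserved sequence) — with copies more
than 92% identical, the margin between those two behaviours is only two
or three bases per arm. Second, *verification*: after editing, one must
argue that the nuclease cut nowhere else. Against a background strain
that differs from the reference assembly at millions of positions, the
absence of off-target damage cannot be read off a variant list directly;
it has to be established by a filter cascade (strain panel subtraction,
zygosity partition, cross-generation intersection) and by a genetic
argument — the backcross dilution law — rather than by any single
statistic.

`talenko` implements both halves as reusable, seeded, fully testable
components, together with a synthetic-data module that generates every
input the pipeline consumes (paralog genomes, edited founders, backcross
pedigrees, strain variants, noisy calls, gapped alignments) with
complete truth records. The package's claims about real data are
deliberately modest: what the test suite shows is that the *procedure*
is correct on data whose ground truth is known, at desk scale.

## The dilution model

The verification logic rests on one Mendelian fact. In a backcross
design (edited female crossed to a wild-type male of the same strain,
repeated each generation), a genuine nuclease-induced variant arises
heterozygous in the founder and is therefore transmitted to each
offspring with probability 1/2; its expected prevalence halves every
generation, and once lost from a line it cannot reappear. A fixed
strain difference against the reference is carried by both parents and
persists in every animal of every generation.

`dilution_test()` formalises this as an absorbing two-state chain per
variant. For a presence pattern $x_1,\dots,x_k$ over $k$ generations,
the likelihood under the induced model with retention $r$ (default 0.5)
is

$$L_\text{induced} = \prod_{g} \begin{cases}
r & x_g = \text{present}, \text{ line still carries} \\
1-r & x_g = \text{absent}, \text{ first loss} \\
1 & \text{after loss (absorbing)} \\
0 & \text{present after loss (impossible)}
\end{cases}$$

and $L_\text{strain}$ is 1 for the all-present pattern, 0 otherwise. A
pattern `present, present, present` therefore has
$L_\text{induced} = 0.5^3 = 0.125$ and $L_\text{strain} = 1$.

The classifier never auto-clears a persistent variant: an all-present
variant found in the strain panel is classed `strain_variant`, but one
*absent* from the panel is classed `needs_validation`, because a
segregating or un-catalogued strain polymorphism is indistinguishable
from an undiluted artifact by pattern alone — only wet validation
(amplicon size comparison, `design_validation_regions()` +
`compare_amplicons()`, or sequencing) can separate them. This mirrors
the situation in which a residue of persistent heterozygous indels
survives all computational filters and is resolved by PCR across each
locus. Patterns with absorbing absence are `induced_candidate`;
reappearance after absence is `inconsistent` (likelihood zero under
both models, i.e. a caller artifact).

No multiple-testing correction is applied: the procedure is a
deterministic filter cascade, not a p-value screen.

## Design choices worth recording

**RVD cipher and arms.** The cipher is positional (NI→A, HD→C, NN→G,
NG→T) with NK as an optional alternative for a 3′ half-repeat T only.
Arms default to 15 recognition bases. Published arm lengths are
sometimes quoted inclusive of the 5′ context T; we count recognition
bases only, and expose the 5′-T context convention as a flag
(`require_5prime_T`) because conventions differ — it defaults to on in
`enumerate_pairs()`, as is standard for TAL effectors. Arm matching is
Hamming-only (no indels): TAL repeats read contiguous bases.

**Paired-site scanning semantics.** "Minimum perfect match" is
interpreted with in-silico-PCR primer semantics: a 3′-anchored
*contiguous exact* match of at least `min_perfect_match` bases per arm,
mismatches allowed 5′ of the anchor — not a best local alignment. The
product is measured from the 5′ end of the left site to the 5′ end of
the right primer's site on the plus axis (amplicon convention), and
both orientations are scanned because FokI dimerisation is
orientation-symmetric. Defaults (8 nt minimum match, 100 bp maximum
product) are the relaxed settings under which an absence of paired hits
is a meaningful negative. Correctness is defined by a brute-force
scalar oracle; the production scanner is an incremental vectorised
implementation checked against the oracle over random genomes across
the full parameter grid.

**Caller quality score.** The minimal caller scores each call as
`10 × support`, capped at 250 — deliberately simple and monotone in
evidence, so the conventional hard cutoff of 100 behaves like a
support threshold (≥ 10 reads). Reproducing any particular production
caller's quality model is a non-goal; only the cutoff semantics matter
to the workflow. Genotype thresholds are the conventional 0.2/0.8
allele-fraction bounds; hemizygous male X loci present all-mutant
pileups and genotype as `1/1`, female heterozygotes as `0/1`, and a
second allele at a site yields the multi-allelic codes `0/2`, `1/2`,
`2/2`. Allele indices follow discovery order at the site, so the code
reflects which catalogued allele is present.

**Indel merging and matching slack.** Evidence within 3 bp and size ±1
is merged (modal position and size win); cross-file matching (strain
panel, generation intersection, truth evaluation) tolerates ±1 bp for
indels, absorbing left-alignment ambiguity, and is exact for SNVs. No
silent lift-over is ever attempted: a panel declaring a different
coordinate system is an error.

**NHEJ outcome model.** Deletion lengths are shifted-geometric with
mean 15 nt, matching the predominance of small deletions among observed
founder alleles; insertions are rare (default probability 0.1) with a
configurable rare long class (~200–300 nt) standing in for the
occasional large insertion allele, whose true size distribution is not
identifiable from a single observed event. Fusion junctions between
paralogs are constructed to carry 2–6 nt of terminal microhomology,
scanning candidate junction placements near the two cut sites and
preferring the configured range — the "terminal microhomology" signature
of NHEJ. The junction finder inverts this exactly: all valid
A-prefix/B-suffix decompositions of an amplicon form one contiguous run
whose width *is* the spanning microhomology, and the junction deletion
`len(A)+len(B)−len(amplicon)` is invariant across the run, so maximal
microhomology is inherent and ties resolve to the leftmost split.

**Mosaicism.** Nuclease activity can persist past the first embryonic
divisions, so an edit may be carried by only a fraction of cells.
Modelled as a per-edit carrier fraction in the founder: transmission
probability is `fraction × 0.5`, and the edit becomes constitutive
(fraction 1) in carriers — which is why secondary mosaic edits disappear
from a line within a couple of generations while founder edits persist.
Whether any real founder off-target was mosaic rather than constitutive
is not knowable from genotype tables alone; both modes are simulatable.

**X-linkage.** The edited family is X-linked and transmitted as one
haplotype block (no recombination within the family is modelled — the
copies span a few kilobases); off-target candidate variants are
autosomal and unlinked. This keeps the transmission arithmetic exactly
the 0.5-per-meiosis law the dilution argument needs.

**Coordinates.** 0-based half-open internally; 1-based in VCF and
SAM-subset output. The boundary is fixed once, at the writers.

## What the simulator does and does not emulate

The generator reproduces the *structure* of the study system: an
X-linked family of three ≥ 92%-identical copies plus a diverged
pseudogene embedded in random flanks; all-or-nothing founder editing
(default founder edit probability 9/19, matching the observed founder
fraction); paralog fusions with microhomology junctions; fixed strain
variants, a configurable fraction of which is withheld from the
published panel (emulating substrain gaps); founder-heterozygous induced
variants for power studies; noisy calls with sign-preserving Gaussian
size errors and Poisson false positives; and uniform-coverage gapped
reads with substitution errors.

It does **not** emulate: sequencing-instrument error profiles or
quality strings; exome capture bias (coverage is uniform);
recombination within the family; alignment ambiguity in repetitive
sequence (alignments are derived from the known edit map, not
realigned). Consequently, a green test suite shows the *analysis logic*
is correct under Mendelian genetics and the stated noise models — it
does not certify caller performance on real reads, which is why the
caller is scoped as "minimal" and the workflow retains the
wet-validation class.

## Numerical and scale choices

Tests and the acceptance script run the simulator at deliberately small
scale, chosen so every stochastic check has analytic error bars:
10,000-offspring litters and 10,000 replicate descent lines put the
binomial standard error at 0.005 (G1) and 0.0033 (G3), so the 50% and
12.5% Mendelian expectations are tested at ±3 SE; structural-variant
recovery uses a ~4.5 kb family chromosome at 30× error-free coverage
over 20 seeds (about 1,300 reads each), where recovery must be exact;
the scanner/oracle equivalence grid uses 100 random genomes up to
100 kb across all 24 parameter combinations; and the fusion recovery
property is exercised on 1,000 simulated junctions, all of which must
round-trip exactly. The end-to-end negative control (no induced
off-targets simulated) must yield a candidate list containing no
truth-labelled induced variant — the package-level restatement of the
study design's expected negative result.

## Limitations

* The dilution likelihood treats generations as single meioses along
  one line; it does not model litter-level sampling or genotyping error.
* Segregating heterozygous strain polymorphisms are not explicitly
  simulated (the strain panel is fixed-difference); they are represented
  in the analysis only through the `needs_validation` class.
* The scanner is exact but not sublinear; it is intended for
  family-scale and synthetic genomes, not a production whole-genome
  screen (though nothing in the semantics prevents it).
* Amplification logic for chimera inference is binary site-presence;
  primer thermodynamics are out of scope.
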