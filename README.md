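# talenko

Design TALEN pairs against families of near-identical paralogs, scan
genomes for paired off-target binding sites, call the engineered
indels/structural variants, and verify the *absence* of off-target
damage by the Mendelian backcross dilution argument — all on seeded
synthetic data with full truth records.

## Who this is for

Genome-editing groups knocking out multi-copy gene families (the
motivating system is an X-linked histone-variant family of three gene
copies that are > 92% identical, plus a pseudogene) and anyone who needs
a tested, self-contained implementation of the pedigree-based
off-target verification workflow: strain-panel filtering, zygosity
partition (0/0, 0/1, 0/2, 1/1, 1/2, 2/2), cross-generation
intersection, and dilution-model classification.

## The core model

In a backcross design (edited female × wild-type male, repeated each
generation) a nuclease-induced variant arises heterozygous in the
founder, so it is transmitted with probability 1/2 per meiosis: its
prevalence halves every generation and, once lost from a line, never
returns. A fixed strain difference persists in every animal. For a
presence pattern over generations, `dilution_test()` computes the
likelihood under both models as an absorbing chain with retention
*r* = 0.5:

    L_induced(present, present, present) = 0.5^3 = 0.125
    L_strain(present, present, present)  = 1

A persistent variant in the strain panel is a `strain_variant`; one
*not* in the panel is `needs_validation` (only wet validation separates
an un-catalogued strain difference from an undiluted artifact); a
pattern with absorbing absence is an `induced_candidate`.

TALEN design uses the RVD cipher (NI→A, HD→C, NN→G, NG→T, optional NK
for the 3′ half-repeat T); off-target scanning uses in-silico-PCR
semantics — a 3′-anchored perfect match of ≥ 8 nt per arm and a maximum
product of 100 bp by default.

## Worked example

Simulate the three-paralog family, engineer the founder deletions of 5,
10 and 64 nt, sequence an edited male in silico at 30×, and call:

```r
library(talenko)
fam <- make_paralog_family(1, copy_labels = c("H2Afb3", "Gm14920", "H2Afb2"))
fam
#> Paralog family on chrX_sim (4500 nt)
#>      gene start  end strand
#> 1  H2Afb3   500 1000      +
#> 2 Gm14920  1500 2000      +
#> 3  H2Afb2  2500 3000      +
#> 4  pseudo  3500 4000      +
#> min pairwise identity: 0.924

hap   <- talenko:::engineer_founder(fam, c(5L, 10L, 64L))
gw    <- apply_edits_to_sequence(fam, hap)
reads <- simulate_reads(gw, sim_params(seed = 1, coverage = 30))
calls <- quality_filter(assign_genotype(call_indels(reads, fam$sequence)))
calls[, c("chrom", "pos", "vtype", "size", "support", "quality",
          "genotype_code")]
#>      chrom  pos vtype size support quality genotype_code
#> 1 chrX_sim  748   DEL    5      35     250           1/1
#> 2 chrX_sim 1745   DEL   10      34     250           1/1
#> 3 chrX_sim 2718   DEL   64      30     250           1/1
```

All three engineered deletions come back at their exact sizes, genotyped
`1/1` as expected for a hemizygous male X. Classifying a variant that
persists across three generations but is absent from the strain panel:

```r
dilution_test(c("present", "present", "present"), in_strain_panel = FALSE)
#> variant NA: [present, present, present] -> needs_validation
#>   (L_induced=0.125, L_strain=1)
```

Parsing the packaged 19-pup founder genotype table shows the
all-or-nothing editing outcome:

```r
recs <- read_genotype_table(system.file("extdata", "founder_genotypes.tsv",
                                        package = "talenko"))
founder_summary(recs)
#> $n_total [1] 19   $n_modified_all_genes [1] 9
#> $n_unmodified [1] 10   $n_partial [1] 0   $n_with_failed_amp [1] 2
```

Nine founders are modified in *all three* genes, ten in none, zero
partially — one TALEN pair edits the whole family or nothing.

The full simulate → design → scan → call → dilute → evaluate workflow is
one call: `run_end_to_end(list(seed = 1, outdir = "run1"))`. A thin CLI
wrapper lives at `inst/scripts/talenko.R`.

## Package layout

| Area | Functions |
|---|---|
| synthetic data | `make_paralog_family`, `sim_params`, `apply_talen_edits`, `simulate_pedigree`, `simulate_variant_calls`, `simulate_reads`, `make_variant_registry` |
| TALEN design | `encode_rvd`, `decode_rvd`, `talen_pair`, `enumerate_pairs`, `classify_specificity` |
| off-target scan | `scan_paired_sites`, `scan_for_pair` |
| SV calling | `call_indels`, `assign_genotype`, `quality_filter` |
| dilution analysis | `strain_filter`, `zygosity_partition`, `intersect_generations`, `dilution_test`, `design_validation_regions`, `compare_amplicons` |
| genotype model | `parse_genotype`, `founder_summary`, `infer_chimera_from_amplification`, `locate_fusion_junction` |
| pipeline | `run_config`, `run_end_to_end`, `evaluate_against_truth` |

See `vignettes/multicopy-knockout-verification.Rmd` for the methods:
the dilution model, matching tolerances, NHEJ/microhomology junction
model, and what the simulator does and does not emulate.
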