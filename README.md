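# mitopair

Analysis of whole mitochondrial genome (mtDNA) variants in matched
blood–tumor pairs.

Tumor cells often carry mtDNA mutations whose abundance — the heteroplasmy
level — can drift between tissues, sometimes reaching homoplasmy in the
tumor. Distinguishing truly somatic mutations from germline variants (and
from low-level artifacts) in matched pairs requires explicit thresholds on
the mutant allele fraction (MAF) in each tissue. `mitopair` implements this
matched-pair workflow for cancer-genomics analysts: classification,
annotation, cohort summaries, haplogroup typing and survival analysis,
plus a synthetic cohort generator with recorded ground truth so every stage
can be validated without access to patient data.

## The model

For a variant observed with `a` alt-supporting reads at depth `d`,
`MAF = a / d` (per tissue; inclusion requires d ≥ 300). With matched blood
(normal) and tumor MAFs, each (patient, variant) record is classified:

- **germline** — blood MAF > 0.01 in at least one cohort patient
  (regardless of its tumor MAF; the evidence propagates to every carrier);
- **somatic** — blood MAF < 0.001 and tumor MAF > 0.01;
- **probable mutation** — blood MAF in [0.001, 0.01] with tumor MAF > 0.01
  (ambiguous origin, excluded from somatic summaries);
- **absent** — detected in neither tissue.

Ploidy status is a step function of MAF: **homoplasmic** if MAF ≥ 0.95,
**heteroplasmic** in [0.01, 0.95), undetected below 0.01. Heteroplasmy
shift is quantified per germline variant as Δ = tumor MAF − blood MAF
across carriers with a two-sided Mann–Whitney U test.

Consequences are annotated on the 16,569-bp rCRS coordinate frame under the
vertebrate mitochondrial genetic code (ATA→Met, TGA→Trp, AGA/AGG→stop),
strand-aware (light-strand genes are read on the complement), with one
consequence per overlapping feature (e.g. the ATP8/ATP6 overlap). Per-gene
burden is normalized as variants per kilobase, `1000 · n / length`.
Haplogroups are scored against a marker panel with the Kulczynski measure
`score = (n_found/n_expected + n_found/(n_found + n_extra)) / 2`.
Survival by somatic burden uses Kaplan–Meier curves, log-rank tests, and a
covariate-adjusted Cox proportional-hazards model (Efron ties).

Note: the bundled reference FASTA (`inst/extdata/rcrs_synthetic.fasta`) is a
**synthetic** sequence on the rCRS coordinate frame — real feature
coordinates, simulated bases pinned to documented variant/codon contexts.
Analyses of real data should supply the true rCRS via
`load_gene_map(fasta = ...)`.

## Worked example

```r
library(mitopair)

map <- load_gene_map()
sim <- generate_cohort(simulation_params(), seed = 42)   # 92 matched pairs
cohort <- mito_cohort(annotate_cohort(classify_origin(sim$records), map),
                      sim$patients)
cohort
#> mito_cohort: 92 patients, 3606 variant records
#> origin
#>          germline           somatic probable_mutation            absent
#>              3347               163                82                14
```

Of 3,606 simulated records, 3,347 are germline observations, 163 somatic
mutations and 82 probable mutations (blood MAF in the ambiguous 0.001–0.01
band arises here from binomial sampling noise on low-heteroplasmy germline
variants). Summaries report explicit numerators and denominators:

```r
bd <- class_breakdown(cohort)
bd$positive_tumors
#>   n_positive n_patients percent
#> 1         67         92    72.8
bd$substitution_class
#>          level   n denominator percent
#> 1   transition 128         162      79
#> 2 transversion  34         162      21
```

So 72.8% of tumors carry at least one somatic mutation, and 79% of distinct
somatic SNVs are transitions. Annotation reproduces documented consequence
calls, e.g. the ND5 missense change at 13333:

```r
annotate_variant(13333, "G", "A", map)
#>   region category strand variant_type substitution_class   effect aa_change aa_pos
#> 1    ND5  protein      H          SNV         transition missense       A/T    333
```

Heteroplasmy shift for one recurrent germline variant, and survival by
burden (mean split at the cohort mean, here 2 mutations):

```r
shift_analysis(classify_origin(sim$records), variant = "663:A>G")
#>   position ref alt n_pairs   mean_delta statistic  p_value n_shift_to_homoplasmy
#> 1      663   A   G      38 0.0007951477       806 0.385659                     1

strata <- stratify_burden(cohort, "mean")
hazard_ratio(strata, c("age", "hr_status"))[c("hr", "ci_lower", "ci_upper", "p_value")]
#> $hr        [1] 1.04478
#> $ci_lower  [1] 0.5100802
#> $ci_upper  [1] 2.139988
#> $p_value   [1] 0.9046822
```

The generator planted no burden effect (log HR = 0), and the fitted hazard
ratio is compatible with 1. A thin command-line wrapper with `simulate`,
`classify`, `summarize` and `survival` subcommands ships in
`inst/scripts/mitopair-cli.R`.

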