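---
title: "Matched blood–tumor mtDNA analysis: models and design choices"
author: "mitopair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched blood–tumor mtDNA analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopair)
```

`mitopair` analyses whole mitochondrial genome variants observed in matched
blood–tumor pairs: it classifies each variant's origin from mutant allele
fraction (MAF) thresholds, calls heteroplasmy/homoplasmy, quantifies
blood-to-tumor heteroplasmy shifts, annotates consequences under the
vertebrate mitochondrial genetic code, summarizes cohorts by gene and tumor
subtype, types haplogroups, and relates somatic mutational burden to
overall survival. This vignette explains the underlying models, the
parameters that matter, and the design decisions taken where the problem
was genuinely open.

## Origin classification

Each (patient, variant) record carries two MAFs, `blood_maf` and
`tumor_maf`, each computed as alt-supporting reads over total depth at the
site; tissues sequenced below 300× at the site are excluded on read. The
classification (`classify_origin()`) is a pure threshold rule:

| class | rule |
|---|---|
| germline | blood MAF > 0.01 in ≥ 1 cohort patient (propagates to all carriers) |
| somatic | blood MAF < 0.001 **and** tumor MAF > 0.01 |
| probable_mutation | blood MAF ∈ [0.001, 0.01], tumor MAF > 0.01 |
| absent | neither tissue above 0.01 |

Two boundary conventions had to be fixed because strict inequalities leave
gaps: a blood MAF of exactly 0.001 is classified `probable_mutation` (the
somatic rule is strict `< 0.001`), and a MAF of exactly 0.95 is
`homoplasmic` (the heteroplasmic band is [0.01, 0.95)). Germline evidence
is propagated at the level of the full variant key (position, ref, alt): a
key with blood MAF > 0.01 in any patient is ineligible to be called somatic
in any other patient. This cohort-level rule mirrors how matched-pair
studies define their somatic class and is what makes singleton/recurrence
counts well-defined at variant level.

The thresholds live in `classification_config()` and can be overridden
(also from the command-line wrapper via `--somatic-normal-max`,
`--somatic-tumor-min`, `--hom-min`). Raising `somatic_normal_max` can only
move records from `probable_mutation` to `somatic`, never the reverse; this
monotonicity is tested.

## Heteroplasmy shift

For each germline variant, `shift_analysis()` reports per-carrier deltas
(tumor − blood MAF), the count of carriers whose tumor reaches homoplasmy
from heteroplasmic blood, and a two-sided Mann–Whitney U test comparing the
blood and tumor MAF distributions across carriers. The U statistic is
computed by `stats::wilcox.test`; for ≤ 8 carriers without ties the exact
null distribution is used, otherwise the normal approximation with tie
correction and continuity correction. Fully tied samples (blood and tumor
MAF vectors identical constants) have zero rank variance; the test is then
vacuous and the p-value is reported as 1. Deltas always compare the same
alt allele in both tissues; no strand flipping is applied.

## Consequence annotation

The bundled gene map uses canonical rCRS coordinates (1-based inclusive,
16,569 bp): 13 protein genes, 22 tRNAs, 2 rRNAs, the D-Loop as a single
circular feature spanning 16024..576, regulatory elements, and explicit
intergenic gap features so that `locate()` is total. Protein annotation is
strand-aware: for light-strand genes (ND6 and eight tRNAs) both alleles are
complemented and codons are read on the complementary strand, with the
reading frame anchored at the gene's initiator codon. Effects are
`synonymous` / `missense` / `nonsense` for SNVs, `frameshift` or
`inframe_indel` for indels by |Δlength| mod 3, and category-level labels
(`tRNA`, `rRNA`, `regulatory`, `dloop_noncoding`, `intergenic`) outside
protein genes. A position covered by several features yields one
consequence per feature — the ATP8/ATP6 overlap (8527..8572) annotates
against both genes, and positions inside both a tRNA and the L-strand
replication origin get both calls. In flat per-record tables a single
primary consequence is kept (protein effects outrank RNA, regulatory, then
non-coding) while `region` lists every covering feature.

Genes whose stop codon is completed by polyadenylation (ND1, ND2, CO3, ND3,
ND4, CYB) carry an `incomplete_stop` flag; variants in the trailing bases
are labelled `stop_region` rather than forced into synonymous/missense.

Three boundary definitions are deliberate choices:

- **D-Loop length** is the canonical 1122 bp (16024..576). Published
  per-kb figures for the control region sometimes imply slightly longer
  boundaries; we keep the canonical span and document it.
- **tRNA-T** is kept at its canonical 66 bp (15888..15953) although some
  printed rate tables imply 65 bp.
- The **LPS regulatory feature** is modeled as 192..445 — the
  promoter-proximal region spanning conserved sequence blocks 1–3 up to the
  light-strand promoter core — so that documented regulatory calls in the
  early control region (e.g. position 207) reproduce. The
  termination-associated sequence (TAS) is 16157..16172 and the L-strand
  replication origin (OLR1) 5721..5798.

### The bundled reference sequence is synthetic

The package ships `rcrs_synthetic.fasta`: a 16,569-base sequence on the
rCRS coordinate frame whose bases are *simulated*, then pinned so that
(a) every variant site documented in the package's tests carries its
published reference allele and codon context, and (b) every protein gene is
a valid ORF on its strand — correct start codons, no internal stops in any
reading frame of the overlap regions, and T/TA tails for the
polyadenylation-completed stops. It supports development and testing
without redistributing the actual reference; analyses of real data should
pass the true rCRS to `load_gene_map(fasta = ...)`. Operations that need
reference bases raise a configuration error when no sequence is loaded
rather than guessing.

The vertebrate mitochondrial genetic code (translation table 2) is built
in-package from the standard code plus its four documented differences
(ATA→Met, TGA→Trp, AGA/AGG→stop); the test suite cross-checks all 64
codons against an independent implementation and verifies the fast
codon-offset annotation path against a brute-force whole-gene retranslation
oracle for an H-strand and an L-strand gene.

## Cohort summaries

`rate_per_kb(count, length)` is `1000·count/length`, kept at full precision
internally; display percentages use half-up rounding to one decimal
(`pct()`), matching the conventional reporting style. Because a "variant"
can mean a distinct position or a distinct (position, allele) pair — the
two differ at multi-allelic sites — `gene_rates()` reports both tallies.
Subtype sharing treats a mutation as a variant key (not patient-specific)
and partitions the somatic universe into a Venn of subtype combinations;
per-subtype mutation rates are normalized by the whole genome length
(16,569 bp). Association testing uses Fisher's exact test for sparse 2×2
tables (any expected count < 5), Pearson chi-square without continuity
correction otherwise; sparse tables larger than 2×2 fall back to chi-square
with a warning. Clustering of patient mutation profiles uses the binary
patient × mutation matrix, Jaccard distance and average linkage, with rows
pre-sorted by patient id so leaf order is deterministic.

## Haplogroup typing

`assign_haplogroup()` scores a blood variant profile against a marker panel
restricted to the panel's universe, with the Kulczynski measure
`(n_found/n_expected + n_found/(n_found+n_extra))/2`. The score is 1 iff
the observed panel-marker set equals the expected set and decreases
strictly with each missing or extra marker; ties break lexicographically
with a flag. Only blood variants with MAF > 0.5 are scored, since
lineage-defining markers are expected (near-)homoplasmic. The bundled
panel is a small fixture covering the seven top-level haplogroups
A, B, C, D, H, J, L with five to seven well-known diagnostic marker
positions each; it is intentionally minimal (no phylogenetic traversal, no
sub-haplogroups) and users can supply a fuller Phylotree-derived panel in
the same TSV format.

## Survival analysis

`stratify_burden()` supports two rules: any-vs-none, and a mean split whose
threshold is the cohort mean burden rounded to the nearest integer (burden
at the threshold goes to the low group). Kaplan–Meier curves, log-rank
tests and Cox models are delegated to the survival package; ties use the
Efron approximation (the original analysis environment did not state its
method; Efron is the better default). The Cox fit reports the burden-group
hazard ratio with a Wald 95% CI, adjusted for caller-specified covariates
(age, stage, hormone-receptor status in the bundled metadata). Cohort-level
hazard-ratio point estimates from any single 92-patient study are not
reproducible without the underlying data; the package instead validates the
machinery by parameter recovery — with a planted hazard ratio of 1.6 at
n = 1000 the Wald interval covers the truth at the nominal rate across
replicates, and log-rank p-values under a planted null are uniform.

## The synthetic cohort generator

`generate_cohort()` emulates the observed structure of a 92-pair breast
cancer study so that the full pipeline can be exercised and validated at
realistic scale. Per patient:

1. a haplogroup backbone is drawn with frequencies A .446, B .228, C .119,
   D .120, L .054, H .022, J .011, and its panel markers are planted as
   homoplasmic germline variants with 5% dropout;
2. additional germline variants are placed uniformly over the genome (no
   hotspots are modeled) up to a count drawn from Normal(37, 9) truncated
   to 16..75; their blood MAF is homoplasmic (≥ 0.95) with probability
   0.55, otherwise low-heteroplasmy Beta(0.8, 25) truncated to
   [0.01, 0.20);
3. heteroplasmic germline variants shift in the tumor with probability
   0.405 (tumor MAF ~ Beta(8, 2), which can reach homoplasmy); unshifted
   variants keep their blood MAF;
4. somatic mutations are absent from blood (true blood MAF 0): 26.1% of
   patients get none, the rest a truncated-geometric count on 1..17 with
   mean ≈ 2.7 (cohort mean ≈ 2, ≈ 74% positive tumors); tumor MAFs are
   homoplasmic with probability 0.214, otherwise Beta(1.3, 3.5) truncated
   to [0.011, 0.95); SNV alt alleles are transitions with probability 0.84
   (0.65 for germline, where the tumor-wide spectrum is less
   transition-rich), and 2–3% of alleles become 1-bp indels;
5. observed read counts are beta-binomial draws at per-site depths uniform
   on 300..6000×, with overdispersion ρ = 0.002 — small enough that
   threshold crossings are dominated by the true MAF;
6. metadata: IHC subtype (LA .633, LB .244, TN .067, H2 .056, ~2% missing),
   age ~ Normal(53.8, 11.5) truncated to 33..92, stage covariates, and
   exponential survival times with administrative censoring uniform on
   30..124 months, with an optional log-HR effect of high burden.

Planted somatic keys additionally avoid any (position, ref, alt) key that
is germline-evidenced elsewhere in the cohort. This is deliberate: the
matched-pair somatic class is *defined* through the cohort-propagated
germline rule, so a ground-truth somatic variant at a germline-evidenced
key is a contradiction in terms — the classification would (correctly)
call it germline, and truth-recovery would be structurally capped.

Ground truth (origin class, true MAFs, planted effect label, backbone
haplogroup, per-patient burden) is recorded alongside the emitted records;
tests compare pipeline output against the truth table only, never against
generator internals. Everything is reproducible from one integer seed.

### What the generator does and does not emulate

It reproduces marginal structure: per-patient variant counts, the MAF
mixtures, class proportions, subtype and haplogroup frequencies, the
transition bias, depth range and sampling noise. It does **not** model
sequencing error (so no artifactual low-MAF calls in blood: the
probable-mutation class arises only from sampling noise around truly
low-heteroplasmy germline variants), mutational hotspots or site-frequency
structure beyond haplogroup markers, linkage between germline variants
other than the backbone, clonal substructure within tumors, or
copy-number effects. Passing recovery tests on these cohorts therefore
demonstrates the correctness of the pipeline's rules and statistics under
the stated noise model, not robustness to every artifact of real
sequencing data.

## Numerical conventions and degenerate inputs

- MAFs outside [0, 1] and alt counts above depth are validation errors;
  zero-depth or sub-300× observations are excluded on read with warnings.
- Indel alleles are normalized on read to the left-aligned parsimonious
  VCF convention (shared suffix then shared prefix stripped, anchor base
  kept), so HGVS-style and VCF-style inputs unify.
- Empty inputs return empty, well-typed results (`shift_analysis()` with
  no carriers, `recurrence()` on an empty cohort, header-only TSVs).
- Fewer than two eligible patients makes clustering an explicit error;
  single-group or event-free survival inputs return non-estimable signals
  rather than fitting artifacts.
- Test problem sizes are chosen for fast, stable validation: 92-patient
  cohorts for recovery checks, pooled cohorts (10 × 92) for the transition
  fraction, 200 replicates at n = 1000 for Cox coverage, and exhaustive
  SNV enumeration over one H-strand (ND1) and one L-strand (ND6) gene for
  the annotation oracle.

## Known limitations

- The bundled reference is synthetic (above); real-data analyses must
  supply the actual rCRS.
- The haplogroup scorer is a panel matcher, not a phylogenetic caller; it
  does not reproduce specialized tools' quality ranks or sub-haplogroup
  resolution.
- Somatic-class inference is purely threshold-based, as in the emulated
  study design; no likelihood-based heteroplasmy caller is provided.
- VCF support expects per-sample `AD`; callers that encode allelic depth
  differently need conversion upstream.
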