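---
title: "Methods: case-control analysis of mitochondrial genome variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control analysis of mitochondrial genome variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoburden)
```

## The analysis problem

Human cells carry hundreds to thousands of mitochondrial DNA (mtDNA)
copies, and a substitution typically affects only a fraction of them
(heteroplasmy). Genotype calls designed for diploid nuclear loci discard
this fraction, yet the biochemical consequence of an mtDNA mutation
depends on its mutant load crossing a *metabolic threshold*. `mitoburden`
therefore works throughout with read-count evidence: an observation is one
sample's support for one substitution, `(position, ref, alt,
mutant_reads, total_reads)` on the 16,569-bp mitochondrial reference
(rCRS / GRCh38 chrM, 1-based coordinates written `m.POS`), and the
heteroplasmic fraction is

$$\mathrm{HF} = 100 \cdot \frac{\text{mutant reads}}{\text{total reads}}.$$

The pipeline compares a case cohort against a control cohort in five
stages: allele grouping with carrier-enrichment testing, a
burden-ratio-stratified kernel association test, pathogenicity annotation
of protein and tRNA alleles, and genotype–phenotype comparison.

## Coordinates, gene map and consequence calling

The 37-gene map (13 protein, 22 tRNA, 2 rRNA genes) ships as
`mt_genes()`, with the two canonical overlaps (MT-ATP8/MT-ATP6,
MT-ND4L/MT-ND4) retained: `assign_gene()` returns every overlapping
symbol and per-gene tables count such alleles once per gene. Positions
outside all genes (chiefly the D-loop) are `noncoding`.

Coding consequences use the vertebrate mitochondrial genetic code
(translation table 2: AUA = Met, UGA = Trp, AGA/AGG = stop) through
`Biostrings`. For the eight light-strand genes the codon is read on the
gene strand, so a genomic `m.5814 T>C` is an `A>G` change in the coding
sequence; reported amino-acid changes use gene-strand codon indices
(`F251L` style). Alleles falling in an incomplete terminal codon (e.g.
the final base of MT-CO3, whose stop codon is completed by
polyadenylation) are rejected, or dropped on request.

Only single-nucleotide substitutions are analyzed; indels are parsed and
flagged `variant_type = "indel"`. Variant input is either a TSV dialect
(`sample, pos, ref, alt, mutant_reads, total_reads`) or VCF 4.x with `AD`
or `DP`+`AF` genotype fields; multi-allelic records split into one
observation per alternate allele, with total depth the sum of the AD
fields.

## Stage 1 — grouping and carrier enrichment

Distinct alleles (keyed by position/ref/alt) fall into three groups:
shared by both cohorts, case-only, control-only. The counting unit of the
enrichment tables is the *carrier*: an individual with at least one
allele of the given gene and group. Shared alleles compare case carriers
against control carriers; case-only and control-only alleles compare the
carrying cohort against the structurally zero other cohort, which is how
a group-specific table is naturally laid out.

The test choice follows the classical expected-count rule: Pearson
chi-square (1 df, **no** continuity correction) when all four expected
cell counts are at least 5, otherwise the two-sided Fisher exact test
(sum of hypergeometric point probabilities not exceeding the observed
table's). This rule is a package decision — validated in the test suite,
where it reproduces published carrier p-values to three significant
figures and matches a complete-enumeration oracle — and both the rule and
the cutoff are arguments of `carrier_enrichment_test()`. The 22 tRNA
genes are pooled into a single `MT-TRNA` region by default, since
individual mt-tRNA genes are too short to accumulate informative carrier
counts. No multiple-testing correction is applied: the stage is
exploratory and raw p-values are reported.

Per-individual allele burdens (`burden_per_individual()`) count distinct
alleles per sample per region — samples without an allele in a region
count zero — and compare cohorts with the Mann-Whitney U test by
default.

## Stage 2 — burden-ratio-stratified SKAT

Because opposite-direction effects can coexist within one gene, each
gene's alleles are first split by the **gene burden ratio**, the case
allele frequency divided by the control allele frequency (carrier
fraction by default; an HF-weighted dosage frequency is available).
Ratio > 1 (including case-only alleles, ratio ∞) defines the positively
associated set; everything else, including exactly equal frequencies, the
negatively associated set. Each non-empty set per gene is tested
separately — running sets jointly would let effects cancel, and the
stratified layout makes the direction of each signal explicit.

### The test

With binary phenotype $y$, null logistic model fitted by iteratively
reweighted least squares giving $\hat\mu$, dosage matrix $G \in [0,1]^{n
\times p}$ and diagonal weights $W$, the score statistic is

$$Q = (y - \hat\mu)^\top G W^2 G^\top (y - \hat\mu),$$

the linear weighted kernel form. Dosages are carrier indicators by
default or HF/100 when requested, reflecting that individual-level allele
fractions — not genotype calls — are the natural unit for heteroplasmic
data. Default weights are the Beta(1, 25) density evaluated at carrier
frequency, the conventional rare-variant upweighting; `weights = 1`
gives a flat kernel. Zero-variance columns are dropped with a warning;
a non-converging or separated null fit is an error with guidance.

Under the null, $Q \sim \sum_j \lambda_j \chi^2_1$, where $\lambda_j$ are
the eigenvalues of $W G^\top P_0 G W$ with
$P_0 = V - VX(X^\top VX)^{-1}X^\top V$, $V = \mathrm{diag}\{\hat\mu_i(1 -
\hat\mu_i)\}$, $X$ the null design. Three p-value routes are exposed:

* `"moment"` — four-moment matching of the mixture to a (noncentral)
  chi-square (the Liu approximation); the default, fast and accurate near
  conventional significance levels.
* `"eigen"` — numerical inversion of the characteristic function
  (Imhof's method) via adaptive quadrature; falls back to the moment
  route if the integral fails to converge.
* `"permutation"` — phenotype-residual permutation,
  $p = (1 + \#\{Q^* \ge Q\})/(B + 1)$, $B = 2000$ by default, seed
  explicit and recorded.

### Calibration and limitations

The test suite checks, under null simulation (n = 156, 10 allele
columns, carrier frequencies uniform on 0.05–0.25, 1000 replicates), that
the rejection rate at α = 0.05 of both the analytic and permutation
routes lies inside the 95% binomial interval around 0.05, that the
analytic p agrees with a 2000-permutation oracle within Monte-Carlo
error, and that a single-column test equals the closed-form logistic
score test. At **ultra-sparse** columns (2–3 carriers) combined with
Beta(1, 25) weights the analytic p-values become conservative (observed
size ≈ 0.03 at n = 156) — never anticonservative; use
`method = "permutation"` when columns are that sparse. Note also that
testing a set *selected* for burden ratio > 1 on the same data is a
selection-biased screen: within-stage p-values rank genes but should not
be read as unconditional error rates.

### Interactions

`interaction_test()` collapses each gene to a weighted burden score
$b = Gw$, fits the null `y ~ b1 + b2`, and score-tests the centred
product term $b_1 b_2$ (1-df chi-square, or permutation). This
burden-by-burden product test is one specific interpretation of
"gene–gene interaction" — the simplest score test with both main effects
controlled — and is flagged as such; collinear or constant burdens are
rejected as degenerate.

## Stage 3 — pathogenicity annotation

**Protein alleles.** Three external tool verdicts per allele arrive as
1–3 stars (neutral / moderate / strong evidence). The combined rating is
the arithmetic mean rounded to the nearest integer; the documented
worked example (2, 2, 3 → mean 2.333 → 2) does not disambiguate exact
halves, so the half rule is configurable and defaults to half-up. The
combination is symmetric and monotone in each input. Alleles with ≥ 2
combined stars **and** HF above the 40% metabolic threshold (strict) are
shortlisted.

**tRNA alleles.** Three criteria, all required:

1. *Rarity* — absent from the analyzed control cohort (not merely the
   reference panel) and strictly below 1% in a reference panel of 2704
   mitochondrial genomes.
2. *Conservation* — conservation index strictly above 75%, where CI is
   the percentage of species in a 17-taxon orthologue alignment (human
   included) carrying the human wild-type base at the position; every CI
   is therefore a multiple of 100/17 (94.12, 88.24, 64.71, ...).
3. *Structural alteration* — the position lies in a cloverleaf stem and
   the substitution converts a Watson-Crick pair (A-U, G-C on the gene
   strand) into a non-Watson-Crick pair. G·U wobble is counted as
   non-Watson-Crick, so creating G·U from G-C is an alteration.
   Anticodon-loop positions (numbers 32–38) are functionally sensitive
   and carry a separate flag, but location alone is deliberately *not*
   treated as an alteration: the package exposes both signals and leaves
   the decision to the configured criterion, since a loop-only variant
   can always be re-flagged downstream.

tRNA structures are tables mapping genomic positions to conventional
cloverleaf numbers, regions and pairing partners. `trna_structure()`
generates internally consistent synthetic cloverleafs (acceptor stem
1–7/66–72, D-stem 10–13/22–25, D-loop 14–21, anticodon stem 27–31/39–43,
anticodon loop 32–38, variable region 44–48, T-stem 49–53/61–65, T-loop
54–60), shrinking the D-loop first and then the variable region for
genes shorter than 72 nt — mimicking real mt-tRNAs' truncated arms.
Curated structure tables can be substituted through the same TSV schema.

## Stage 5 — genotype–phenotype comparison

Within the case cohort, carriers of the flagged allele set are compared
with non-carriers variable by variable: Mann-Whitney U for continuous
phenotypes (exact distribution when the smaller group has ≤ 8 values and
no ties, normal approximation with tie correction otherwise — the exact
branch equals full label-permutation enumeration), Fisher exact for
binary traits. Student's t is available on request, and
`ttest_from_summary()` reproduces two-sample t tests (pooled or Welch)
from published summary statistics alone; at the printed precision both
variants agree on the cohort age example (p = 0.996). A power simulation
in the test suite shows that an HDL-sized shift (Δ = 14 mg/dl, SD 12.5)
at 4 versus 48 carriers sits at the edge of detectability (median p
between 0.01 and 0.10) — small carrier groups make these comparisons
fragile by design.

## The synthetic cohort generator

`generate_cohort()` exists so that every stage runs, and is tested,
without protected cohort data. Its defaults encode the target study
design: 52 cases, 104 age-matched controls. Alleles arise from two
layers:

* a **shared population pool** of 450 sites whose frequencies follow a
  two-component 1/f spectrum (55% from [0.004, 0.03], 45% from
  [0.03, 0.25]), carried by independent Bernoulli draws per sample; and
* **cohort-private singletons**, Poisson(2.6) per sample.

These values were fitted analytically (before any test was written) so
the expected distinct-allele counts reproduce the design's reported
scale — about 442 case alleles, 638 control alleles, 278 shared — with
roughly 65% of cohort alleles in the low-frequency band. Under
independent Bernoulli carriage those four marginals cannot all be hit
exactly at once; the compromise leans toward the allele counts. Read
depths follow a normal (mean 3251.22, SD 964.63) truncated to
[2027.23, 5612.43] — the truncation shifts the realized mean to ~3400,
and tests compare against the truncated-normal expectation.
Heteroplasmic fractions are bimodal: 70% near-homoplasmic (uniform
95–100%) and 30% intermediate (uniform 40–80%). Causal genes get an
odds-scale carrier enrichment in cases, and an HDL shift (default
+14 mg/dl) for carriers feeds the phenotype stage. An optional planted
tRNA allele — case-only, HF 99%, stem-disrupting, CI 16/17, panel count
1 — gives end-to-end truth-recovery tests their target.

What the generator does **not** emulate: haplogroup structure and
linkage between sites (carriage is independent), platform- or
alignment-specific artefacts, sequencing error in read counts, and
strand- or position-dependent depth. Passing tests therefore demonstrate
the pipeline's statistical behaviour under its own model assumptions,
not robustness to those real-data features.

Identical seeds give byte-identical cohorts; the seed is recorded in the
output and in the pipeline manifest.

## Numerical and policy choices

* All thresholds are strict inequalities (> 40% HF, > 5% common band,
  < 1% panel, > 75% CI, ratio > 1), matching their verbal definitions;
  boundary values fall on the conservative side, and all are arguments.
* Expected-count cutoff 5 for the chi-square/exact switch; configurable.
* Eigenvalues below `1e-10` of the largest are discarded; Imhof
  integration uses `rel.tol = 1e-9` with the moment route as fallback;
  permutation p-values are floored at 1/(B+1).
* Frequencies at 0 or 1 are nudged by 1e-8 before Beta-density
  weighting.
* HF is computed per observation; when one sample shows an allele more
  than once, dosage matrices take the maximum HF.
* Ties in dosage columns, empty allele sets, all-zero matrices and
  empty regions degrade to Q = 0 / p = 1 / skipped rows rather than
  errors; impossible inputs (mutant reads exceeding depth, ref equal to
  alt, zero cohort) are errors.

## Problem sizes in the test suite

The suite (about four minutes) uses: 1000-replicate null calibrations
for SKAT (permutation B = 300 inside the calibration, B = 2000 for the
oracle comparison) and the Mann-Whitney comparison; exhaustive
Fisher-versus-enumeration checks over all 2×2 tables with cohort sizes
≤ 14 plus 300 random tables up to size 30; 20-replicate causal-gene
recovery; and full-pipeline runs on default-sized synthetic cohorts
(156 samples, ~1200 observations).

## Known limitations

* The synthetic reference sequence is random apart from anchored
  example positions; it is not the rCRS. Analyses of real data must load
  a real reference FASTA.
* Generated cloverleafs follow the canonical layout, not curated
  per-gene structures; conventional numbers for irregular tRNAs can
  deviate from curated tables.
* The burden-ratio stratification reuses the data that SKAT then tests
  (selection bias; see Stage 2).
* Small-sample conservatism of analytic SKAT p-values at ultra-sparse
  columns; use permutation there.
* No multiple-testing correction anywhere; the pipeline is a screen.
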