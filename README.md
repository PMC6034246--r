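# mitoburden

Case-control burden and pathogenicity analysis of mitochondrial genome
variants called from deep sequencing.

Mitochondrial DNA is present in hundreds to thousands of copies per cell,
so a variant affects a *fraction* of molecules (heteroplasmy) rather than
producing discrete genotypes, and its phenotypic effect depends on whether
the mutant load crosses a metabolic threshold. `mitoburden` implements a
complete analysis pipeline for this setting, aimed at statistical
geneticists and bioinformaticians comparing mtDNA substitution spectra
between a case cohort and a control cohort:

1. **Heteroplasmy and banding** — per-observation heteroplasmic fraction
   `HF = 100 · mutant_reads / total_reads`, a strict 40% metabolic
   threshold flag, and a 5% common/low-frequency carrier band.
2. **Allele grouping and carrier enrichment** — distinct alleles are
   partitioned into shared / case-only / control-only groups; per gene and
   group, the 2×2 carrier table is tested with the Pearson chi-square test
   (no continuity correction) when all expected counts are ≥ 5 and the
   two-sided Fisher exact test otherwise.
3. **Burden-ratio-stratified SKAT** — each gene's alleles are split into
   positively associated (case/control frequency ratio > 1) and negatively
   associated sets; each set is tested with a sequence kernel association
   test whose score statistic is

   `Q = (y − μ̂)ᵀ G W² Gᵀ (y − μ̂)`

   with `y` the binary phenotype, `μ̂` the null logistic fit, `G` the
   sample-by-allele dosage matrix (carrier 0/1 or HF/100) and `W` diagonal
   Beta(1, 25) weights on carrier frequency. Under the null, `Q` is a
   weighted sum of 1-df chi-squares; p-values come from four-moment
   matching, characteristic-function inversion (Imhof), or permutation.
   A burden-by-burden score test probes gene–gene interactions.
4. **Pathogenicity annotation** — protein alleles: three tool ratings
   (1–3 stars) combined by averaging-and-rounding, shortlisting alleles
   with ≥ 2 stars and HF > 40%; tRNA alleles: potentially pathogenic iff
   absent from controls and < 1% in a 2704-genome reference panel,
   conservation index > 75% across a 17-species orthologue alignment, and
   a structural alteration on the cloverleaf (a stem substitution breaking
   a Watson-Crick pair, with G·U counted as non-Watson-Crick).
5. **Genotype–phenotype comparison** — clinical variables compared between
   carriers and non-carriers of flagged alleles (Mann-Whitney U for
   continuous, Fisher exact for binary), plus a summary-statistics t test.

A synthetic-cohort generator (`generate_cohort()`) emulates the intended
study design — 52 cases vs 104 controls, a 1/f allele-frequency spectrum
with an excess of low-frequency alleles, bimodal heteroplasmic fractions,
truncated-normal read depths — together with every ancillary input
(phenotypes, tool ratings, panel counts, conservation alignments, tRNA
cloverleaf tables), so the whole pipeline runs and is testable without any
protected data.

## Worked example

```r
library(mitoburden)

co  <- generate_cohort(simulation_config(seed = 1,
                                         causal_genes = "MT-CO3",
                                         causal_or = 3))
obs <- co$observations

dplyr::count(assign_groups(obs), group)
#>   group            n
#> 1 case_only      165
#> 2 control_only   324
#> 3 shared         284

carrier_enrichment_test(10, 52, 0, 104)
#>   k_case n_case k_ctrl n_ctrl statistic    p_value method
#> 1     10     52      0    104        NA 0.00000903 fisher_exact

skat_by_gene(obs, reference = co$reference, genes = "MT-CO3")
#>   gene   allele_set n_alleles     Q   p_value method
#> 1 MT-CO3 negative          14  909. 0.835     moment
#> 2 MT-CO3 positive          21 6665. 0.0000540 moment
```

The grouping table counts distinct substitutions by cohort sharing (284
seen in both cohorts here). The enrichment call reproduces the carrier
test for 10 of 52 cases versus 0 of 104 controls: the expected-count rule
selects the Fisher exact test and returns p = 9.03×10⁻⁶. The SKAT table
shows the planted causal gene detected through its positively associated
allele set (p = 5.4×10⁻⁵) while its negatively associated set stays null.

The full pipeline is one call (or
`Rscript inst/scripts/mitoburden.R all --config config.yaml`):

```r
report <- run_pipeline(co, pipeline_config(seed = 1, outdir = "results"))
```

which writes the enrichment, association, annotation and phenotype tables
plus a JSON run manifest.

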