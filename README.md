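# poipanel

Gene-panel variant interpretation for premature ovarian insufficiency (POI)
cohorts.

POI — loss of ovarian function before age 40 with FSH repeatedly above
25 IU/L — is genetically heterogeneous: dozens of genes spanning meiosis,
ovarian transcription factors and hormone ligand/receptor signalling each
explain a small fraction of patients, under different inheritance modes.
Targeted panel screens of POI cohorts therefore need a reproducible path
from an annotated per-genotype variant table to per-patient molecular
diagnoses and cohort-level statistics. `poipanel` implements that path for
clinical geneticists and researchers running such screens:

1. **Consequence categorization** from HGVS cDNA/protein notation
   (missense, nonsense, frameshift, canonical/non-canonical splice; the
   canonical splice window is ≤ 2 intronic bp from the exon boundary).
2. **Rarity filtering**: keep variants with allele frequency < 0.1% in the
   global 1000 Genomes and gnomAD references (missing frequencies pass;
   the comparison is strict).
3. **Simplified ACMG-style classification**:
   - *Pathogenic (P)*: nonsense, frameshift, canonical-splice, or
     previously reported pathogenic variants;
   - *Likely pathogenic (LP)*: missense with MetaSVM "Deleterious"
     combined with CADD > 3 or DANN > 0.95;
   - *VUS* otherwise.
4. **Causality assignment** under per-gene inheritance modes (AD, AR,
   AR/AD, XLD): dominant single hets, recessive homozygotes and compound
   heterozygotes (trans assumed when unphased, pedigree-confirmed when
   phased), the MSH4–MSH5 digenic-heterodimer rule for paired lone hets in
   the partner genes, and an **oligogenicity** call when P/LP variants span
   ≥ 2 genes.
5. **Cohort statistics**: per-gene/per-variant carrier prevalence, novelty
   tallies, exact (hypergeometric) carrier-frequency enrichment against
   reference populations, and monogenic-vs-oligogenic phenotype
   comparisons (one-way ANOVA; chi-square with exact-test fallback).
6. **Synthetic cohorts**: a generator that plants causal genotypes under
   stated mechanisms with burden-dependent phenotypes, for end-to-end
   validation of every stage.

The package ships a curated 28-gene POI panel (11 meiosis genes, 8
ligand/receptor genes, 9 transcription factors) and a fully transcribed
72-patient example cohort carrying 61 unique P/LP variants.

## Worked example

```r
library(poipanel)

cohort <- poi_example_cohort()   # 72 patients, 91 genotype observations
res <- run_poi_pipeline(cohort, cohort_n = 500)
res
#> <poi_pipeline>
#>   rare variants kept: 61 (rejected: 0)
#> <poi_summary>
#>   72 / 500 patients carry P/LP variants (14.4%)
#>   61 unique P/LP variants (18 P, 43 LP) in 19 genes; 58 novel
#>   63 monogenic, 9 oligogenic patients
```

Of 500 screened patients, 72 (14.4%) carry at least one pathogenic or
likely pathogenic panel variant; the 61 distinct variants fall in 19 of
the 28 genes, and 58 of them are novel (not previously reported in POI).
Nine patients carry qualifying variants in two or more genes.

Per-gene prevalence and the recurrent FOXL2 variant:

```r
dplyr::filter(tidy(res$summary), gene %in% c("FOXL2", "NOBOX"))
#> # A tibble: 2 × 4
#>   gene  carriers fraction category
#>   <chr>    <int>    <dbl> <chr>
#> 1 FOXL2       16    0.032 transcription_factor
#> 2 NOBOX        6    0.012 transcription_factor

enrichment_test(13, 500, ref_af = 0.0008, ref_alleles = 5008)
#> <poi_enrichment> two-sided exact hypergeometric test
#>   unit: allele  cohort 13/1000 (0.0130) vs reference 4/5008 (0.0008)
#>   odds ratio = 16.5, p = 8.65e-08
```

The 13 carriers of FOXL2 c.1045C>G (p.R349G) represent a carrier
frequency far above the reference allele frequency of 0.08% — strong
enrichment in the POI cohort.

Synthetic validation:

```r
spec <- simulation_spec(n_patients = 500, seed = 42)
sim <- simulate_cohort(spec)
out <- run_poi_pipeline(sim, cohort_n = 500)
evaluate_recovery(sim, out$assignments, out$classified)
#> <poi_recovery>
#>   explained:  sensitivity 1.000, specificity 1.000
#>   oligogenic: sensitivity 1.000, specificity 1.000
```

A thin command-line wrapper is installed at `inst/cli/poipanel.R` with
subcommands `classify`, `assign`, `summarize`, `simulate` and `reproduce`.

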