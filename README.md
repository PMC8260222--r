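# esmscreen

Statistical discovery of **endogenous sources of mutation (ESMs)** — genes
whose products damage genomic DNA from within — from tumor-cohort data,
plus analysis of the bacterial fluctuation assay used to validate such
candidates.

The motivating setting is clear-cell kidney carcinoma (KIRC), whose
mutation spectrum (low CG-site share, elevated C>A/G>T transversions)
is poorly explained by the classical deaminase ESMs. The logic is simple:
if a gene product mutagenizes DNA, patients expressing more of it should
carry more of the corresponding mutations. Given a somatic substitution
catalog and an expression matrix for the same cohort, `esmscreen`:

1. builds per-sample substitution spectra over the 12 base changes and
   their 6 complementary-collapsed (*c-substitution*) classes, with
   optional coding-strand resolution and base-composition normalization;
2. runs three screens per gene *g* against the burden
   *m<sub>i</sub>* of a chosen class in patient *i*:
   * Spearman correlation r(expr<sub>g</sub>, m) with two-sided p from
     the t approximation,
   * two-tailed Student *t* between the highest and lowest burden
     tertiles with FC = mean(high)/mean(low),
   * the same *t* contract between mutation-status classes (e.g. VHL
     C>A/G>T carriers vs non-carriers);

   candidates are the top-*k* (default 200) genes at raw p < 0.05, and
   the candidate ESMs are the intersection across screens;
3. quantifies transcriptional strand asymmetry — a single-strand-DNA
   mutator yields r(coding C>A) > r(coding G>T) because the transcribed
   template strand is protected — including a 2–5 group-number sweep;
4. stratifies survival by expression (Kaplan–Meier, log-rank, median and
   best-separation splits, the latter with an explicit unadjusted-minimum
   caveat);
5. quantifies Luria–Delbrück rifampicin-resistance fluctuation assays:
   median resistant frequency per 10⁹ viable cells, positional rpoB
   substitution calling, hotspot ranking, spectrum-shift tests, and a
   reproducible culture simulator.

A synthetic-cohort generator (`simulate_cohort()`, `simulate_clones()`,
`simulate_survival()`) emulates the statistical structure of a
532-patient KIRC-like study with planted effects, so every stage is
testable without external downloads.

## Worked example

```r
library(esmscreen)

co   <- simulate_cohort(cohort_spec(), seed = 1)   # 532 patients, 200 genes
norm <- tbp_normalize(co$expression)               # housekeeping-normalized
prof <- count_profiles(co$mutations, roster = colnames(norm))

round(cohort_csub_frequencies(prof), 3)
#> C>A/G>T C>G/G>C C>T/G>A A>C/T>G A>G/T>C A>T/T>A
#>   0.249   0.050   0.402   0.071   0.149   0.079

sc <- spearman_screen(norm, prof, type = "C>A/G>T")
head(as.data.frame(sc), 3)
#>   gene statistic        p        q rank
#> 1 G001    0.4251 9.28e-25 1.86e-22    1
#> 2 G009    0.0865 4.60e-02 9.12e-01    2
#> 3 G106    0.0839 5.31e-02 9.12e-01    3
```

The planted mutator G001 tops the correlation screen (r = 0.43, the
generator targets a true rank correlation near 0.5). Intersecting the
three screens' candidates:

```r
tt <- ttest_screen(norm, group_by_burden(prof, g = 3))
ms <- mutation_status_screen(norm,
        sample_mutation_status(co$mutations, "G002", roster = colnames(norm)))
candidate_overlap(select_candidates(sc), select_candidates(tt),
                  select_candidates(ms))$genes
#> [1] "G001" "G024"
```

G001 survives all three screens (G024 is a chance co-survivor — with 200
genes at alpha = 0.05 a small number of false intersections is
expected). The spectrum-shift worked example — control clones with 2/32
focal-class calls versus treated clones with 25/36 — uses the
continuity-corrected chi-squared:

```r
compare_spectra(c("C>A/G>T" = 2, rest = 30),
                c("C>A/G>T" = 25, rest = 11))$p.value
#> [1] 4.026e-07
```

and survival stratification by the planted gene separates the arms:

```r
arm <- split_median(setNames(norm["G001", ], colnames(norm)))
#> median OS low: 54 months, high: 24.6 months
#> log-rank chisq 52.2, p = 5e-13
```

High expression of the planted mutator is linked (through the
generator's hazard model) to shorter survival, the pattern expected of a
clinically relevant ESM.

## Documentation

The methods vignette (`vignettes/esm-discovery.Rmd`) documents the
statistical conventions (tie handling, continuity correction, selection
rules), the synthetic generator's assumptions and what they do and do
not establish about real data, and known limitations.
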