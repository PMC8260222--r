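---
title: "Screening tumor cohorts for endogenous sources of mutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening tumor cohorts for endogenous sources of mutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(esmscreen)
```

## The problem

Somatic mutations in tumors arise both from external mutagens and from
*endogenous sources of mutation* (ESMs) — cellular factors, typically
enzymes, that damage genomic DNA from within. The canonical examples are
the AID/APOBEC deaminases, which leave a C>T-rich footprint at CG
dinucleotides. Some tumor types, however, carry mutation spectra that
deamination cannot explain; clear-cell kidney carcinoma (KIRC) is the
standard example, with a low share of CG-site mutations, low APOBEC
expression, and an elevated share of C>A/G>T transversions.

`esmscreen` implements a statistical route to candidate ESMs that needs
only two per-patient measurements available in any modern tumor cohort:
a somatic substitution catalog and a gene-expression matrix. If a gene
product damages DNA, patients expressing more of it should carry more of
the corresponding mutations. The package builds substitution spectra,
runs three complementary expression-versus-burden screens, intersects
their candidates, quantifies transcriptional strand asymmetry,
stratifies survival, and analyzes the bacterial fluctuation assay used
to validate candidates experimentally. A synthetic-cohort generator with
planted effects makes every stage testable end to end.

## Substitution spectra

A substitution is one of 12 ordered base changes (`sub_types()`). Without
strand information a change and its reverse complement are
indistinguishable, so catalogs are collapsed 2-to-1 onto six
*complementary substitution* (c-substitution) classes (`csub_types()`):
C>A/G>T, C>G/G>C, C>T/G>A, A>C/T>G, A>G/T>C, A>T/T>A. Mutation TSVs
report ref/alt on the genomic plus strand, following MAF convention.
When a record's gene strand is known, `strand_resolve()` re-expresses it
on the gene's coding (untranscribed) strand: a plus-strand C>A in a
minus-strand gene is a coding G>T. `count_profiles()` tallies all three
views per sample — 12-channel genomic, 6-channel collapsed, and
12-channel coding-strand (strand-unknown records are excluded from the
stranded view only, with a reported tally).

Spectra can be normalized by the base composition of the relevant
reference sequence. The per-site convention is: a C/G-rooted class count
is divided by the number of C plus G sites, an A/T-rooted class by A
plus T sites, and a stranded class by the count of its own reference
base. This is the simplest defensible reading of "normalization by base
frequency"; the exact formula is not standardized in the literature, so
we chose the one with a round-trip identity (rates times site counts
recover counts exactly) and document it as an assumption.

Two spectra are compared with `compare_spectra()`. On a 2x2 collapse
(focal class versus rest) the chi-squared statistic uses the Yates
continuity correction; larger tables use the uncorrected statistic.
This choice is deliberate: on the worked 2x2 example shipped with the
package (2/30 versus 25/11 focal-class calls) the corrected test gives
p = 4.0e-7 while the uncorrected gives about 1e-7, and the corrected
value is the one consistent with the published analysis of that table.
Fisher's exact test is two-sided in the usual "sum of tables at most as
probable" sense; sidedness conventions differ across software, so this
is stated rather than assumed.

## The three screens

All screens operate on housekeeping-normalized expression
(`tbp_normalize()`; TATA-binding protein by default, a common choice for
cross-sample normalization because of its stable expression). Values
stay on the linear scale: the fold change reported by the group screens
is a ratio of means, so a log transform would change its meaning. A log2
option exists for volcano output only.

1. **Correlation screen** (`spearman_screen()`): per gene, Spearman rank
   correlation between expression and the per-sample burden of a chosen
   mutation class, with average-rank ties and a two-sided p from the
   t-distribution approximation. Rank correlation is used because burden
   distributions are heavily skewed and the relationship need only be
   monotone.
2. **Burden-group screen** (`group_by_burden()` + `ttest_screen()`):
   patients sorted by burden (ties broken by sample id, so the split is
   deterministic) and cut into g near-equal groups (g = 3 by default;
   lower groups receive the extras when sizes cannot be equal). Each
   gene is tested between the extreme groups with a two-tailed
   equal-variance Student t (the convention of the analyses this package
   reproduces; Welch is available via `var_equal = FALSE`), and
   FC = mean(high)/mean(low).
3. **Mutation-status screen** (`mutation_status_screen()`): the same
   t-test contract between carriers and non-carriers of a mutation class
   in a gene of interest — e.g. VHL C>A/G>T carriers in KIRC
   (`sample_mutation_status()` builds the status vector).

`select_candidates()` keeps genes with raw p below 0.05 and truncates to
the top 200 by the screen statistic (r or FC, descending). That mirrors
the "top-ranked ~1% of genes" selection the screens are modeled on; the
published selection rule does not state whether ranking used the
statistic or p, nor whether negative correlations were eligible, so both
are exposed (`rank_by`, and ranking is by signed statistic — positive
correlates — by default, since an ESM is hypothesized to *increase*
mutations). Benjamini-Hochberg q-values are computed and carried in
every result table but never drive selection; they are reported because
modern readers expect them. `candidate_overlap()` takes the strict
intersection across screens (ordered by mean within-screen rank) and
reports all Venn region sizes.

## Transcriptional strand asymmetry

A mutator that attacks single-stranded DNA preferentially damages the
untranscribed (coding) strand, because the transcribed template strand
is intermittently protected by the transcription machinery and nascent
RNA. A C lesion on the coding strand yields a gene-level C>A; the same
lesion on the template strand yields G>T. `stranded_correlations()`
therefore compares the focal gene's correlation with coding C>A versus
coding G>T burden, and `group_sweep()` repeats the group t-test over
g = 2..5 to show the association is not an artifact of one grouping
resolution. The report includes all 12 stranded classes, not only the
headline pair, so symmetry can be audited. Records without a known gene
strand are excluded from stranded classes but retained in `"total"`.
One caveat is inherent to the design: stranded class burdens share each
patient's total mutation load, so even a strand-neutral class correlates
weakly with the focal gene; the signature of a coding-strand mutator is
the *gap* r(C>A) > r(G>T), not a zero G>T correlation. Whether such
correlations should use all samples or only mutation-bearing samples is
not standardized; the package uses all samples.

## Survival stratification

`km_estimate()` wraps the product-limit estimator with Greenwood
standard errors and plain (linear-scale) confidence bands; at tied
times, events are processed before censorings. The median survival is
the smallest *event* time with S at or below one half, `NA` when the
curve never gets there. `logrank_test()` is the standard 1-df two-group
test; with zero events it returns p = 1 with a warning rather than
failing, since downstream cutpoint scans may legitimately produce such
groups.

Two expression splits are provided. `split_median()` assigns ties to the
low group (deterministic and conservative for the high-expression-is-bad
hypothesis). `split_best()` scans every distinct expression value
between the 10th and 90th percentiles — a documented convention; the
admissible range is rarely stated in published best-separation analyses —
and returns the cutpoint minimizing the log-rank p. That minimum is
reported **unadjusted**, with an explicit caveat field: under the null
it is strongly anti-conservative (the package's own null simulation in
the test suite shows the minimum p falling below 0.05 several times more
often than a calibrated test would), and no minP correction is applied
because the package mirrors the analysis convention it models. Treat
best-separation p-values as descriptive.

## Fluctuation assay

The rifampicin-resistance assay measures a gene's capacity to cause
mutations in E. coli: resistance arises from substitutions in rpoB, so
the per-culture frequency of resistant colonies per 1e9 viable plated
cells, summarized as the median over parallel cultures (30 in the
standard design), quantifies mutagenesis. The median — midpoint-averaged
for even culture counts — is used instead of the mean because of
Luria-Delbruck "jackpot" cultures in which an early mutation founds a
large resistant clone. `call_substitutions()` compares sequenced rpoB
amplicons (627 bp in the standard design) to the reference positionally;
indels are out of contract and fatal, ambiguity codes skip the position
with a tally. `clone_spectrum()` feeds the per-arm spectra into
`compare_spectra()`, and `hotspot_counts()` ranks recurrent positions
(descending count, ties by ascending position).

`ld_simulate()` is a discrete-generation culture model: each cell
divides once per generation, each wild-type daughter mutates with
probability mu, and mutant lineages double deterministically.
Back-mutation and mutant fitness costs are ignored — both are negligible
over an overnight culture. Plating defaults to the whole final
population because plating dilutions vary between protocols; a
`plating_fraction` parameter subsamples binomially when needed. The
model reproduces the two qualitative signatures that matter: the median
frequency increases with mu, and the mean per-culture frequency exceeds
the median (jackpot skew).

## The synthetic cohort generator

`simulate_cohort()` emulates the shape of a KIRC-like discovery cohort,
and its defaults *are* the study conditions the package is tested under:

* 532 patients, 200 genes (the gene count is scaled down from
  genome-wide; the screens are per-gene and independent, so a smaller
  panel changes only multiplicity, which the null-calibration tests
  measure directly);
* per-patient burden ~ negative binomial with mean 57 (about 30,300
  substitutions in total, matching the cohort scale emulated) and size 2,
  giving the strong overdispersion real burdens show;
* a 6-class mix with 0.40 on C>T/G>A — the dominant class in all major
  cancers — and elevated C>A/G>T (0.25), A>T/T>A (0.08) and A>C/T>G
  (0.07), the KIRC-like signature, split evenly within each
  complementary pair;
* one planted gene whose expression is
  `baseline * exp(beta * z + N(0, noise_sd))`, with `z` the standardized
  burden of a chosen link class. Expression is conditioned on burden
  (not vice versa) because the screens are correlational and
  direction-agnostic; this makes recovery tests well-posed. With
  `noise_sd = 1` the default `beta = 0.6` targets a true rank
  correlation near 0.5 via the Gaussian-copula identity
  rho = beta / sqrt(beta^2 + noise_sd^2);
* a VHL-like "status" gene receiving 5% of all mutation assignments,
  which yields a carrier fraction near 50% — the mutation-status screen
  needs a frequently hit gene, exactly as the analysis it emulates used
  VHL, the most frequently mutated gene in KIRC;
* exponential survival (hazard ratio 2.5 for high planted-gene
  expression, baseline 0.01/month, censoring 0.008/month), giving
  median survivals and censoring fractions in the range typical of
  multi-year oncology cohorts.

Setting `link_class = "C>A"` makes the planted gene a coding-strand-only
mutator for asymmetry tests; `beta = 0` gives a fully null cohort used
to check screen calibration (the observed false-positive rate at
alpha = 0.05 must sit in 0.05 +/- 0.02).

What the generator does **not** emulate — and therefore what passing
recovery tests do not show — includes: realistic per-gene expression
covariance (genes are independent log-normal), trinucleotide mutation
context, positional hotspot landscapes in the cohort catalog,
tumor purity and coverage variation, and any confounding between burden
and expression through a third variable. The screens contain no
covariate adjustment by design, so on real data they inherit the usual
caveats of correlational evidence.

`simulate_clones()` plays the same role for the fluctuation module:
arm-specific type mixes (transition-dominated control, C>A-shifted
treated arm), a Poisson number of substitutions per clone, and optional
positional hotspots with multiplicative enrichment among positions whose
reference base matches the drawn type. A truth table of planted calls
supports exact round-trip tests of the caller.

## Numerical and degenerate-input conventions

* Genes with zero expression variance are skipped by the correlation
  screen (tallied, not silently dropped); genes constant in both t-test
  groups report p = 1 and are flagged.
* FC is missing (`NA`) when the low-group mean is zero; it is never
  clamped.
* Burden grouping, median splits and candidate ordering break every tie
  deterministically (by sample id or gene name), so identical inputs
  give byte-identical outputs.
* All positions are 1-based inclusive; readers enforce this and reject
  or tally malformed rows rather than repairing them.
* Simulators take an explicit seed and are reproducible to the byte;
  no function reseeds the global RNG behind the caller's back otherwise.

## Problem sizes used by the test suite

The shipped tests run the recovery and calibration experiments at 20
seeds with the full 532-patient default cohort, the oracle-equivalence
checks at 100 random small instances per statistic (tolerance 1e-10
against brute-force implementations), and the fluctuation properties at
30 cultures x 10 meta-replicates. These sizes keep the full suite under
a minute on a laptop while leaving the binomial error of every
fraction-type check far below its acceptance margin.

## Known limitations

* The package analyzes 6/12-channel spectra only; no trinucleotide
  (96-channel) signatures and no signature-fitting against external
  catalogs.
* No covariate adjustment, purity correction, or per-sample coverage
  normalization in the screens.
* No Cox models; survival analysis is KM + log-rank only.
* The fluctuation module reports median frequencies, not
  maximum-likelihood mutation-rate estimates (no Ma-Sandri-Sarkar
  estimator).
* `split_best()` p-values are unadjusted minima; see above.
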