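---
title: "Virus-host abundance scaling: models, permutation inference and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virus-host abundance scaling: models, permutation inference and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhratio)
```

## The scientific problem

Marine metagenome surveys yield relative-abundance estimates for viral
groups and for their putative microbial hosts across sampling sites. A
recurring question is whether virus abundance $y$ rises with host abundance
$x$, and if so how steeply. On log10 axes a power law $y \sim x^\alpha$
appears as a line of slope $\alpha$: $\alpha > 0$ means viruses track their
hosts, and $0 < \alpha < 1$ means the increase is sublinear, the pattern
predicted by "Piggyback-the-Winner" style arguments in which lysogeny
becomes more prevalent at high host density.

Many analyses instead regress the virus-to-host ratio (VHR) on host
abundance. Writing $y/x \sim x^\beta$, algebra gives $\beta = \alpha - 1$
identically. The pitfall is that when $y$ is *unrelated* to $x$
($\alpha = 0$), the ratio regression reduces to fitting $1/x$ against $x$
and returns a slope of $-1$ on log-log axes. A strongly negative VHR slope
is therefore compatible with no virus-host relationship at all; this is the
classic *spurious self-correlation* of a ratio with its own denominator.
Distinguishing $\beta \approx -1$ caused by real sublinear coupling from
$\beta \approx -1$ caused by independence requires testing $\alpha > 0$
directly, which is what this package operationalises.

## The procedure

For each virus-host pair the pipeline:

1. **Filters** sites: any site with zero virus or zero host abundance is
   dropped (both abundances must be positive for the paired log-scale
   statistics), and a pair is analysed only if at least `min_sites = 5`
   positive sites remain. Five is the study-design inclusion rule, not a
   mathematical requirement; the hard floor is 2, below which no slope
   exists.
2. **Fits** the least-squares line of $\log_{10} y$ on $\log_{10} x$
   (`loglog_fit()`, giving $\hat\alpha$, the product-moment correlation $r$
   and Spearman's $\rho$) and the companion ratio regression of
   $\log_{10}(y/x)$ on $\log_{10} x$ (`ratio_fit()`, giving $\hat\beta$).
   `theil_sen_slope()` provides a robust nonparametric slope (the median of
   pairwise slopes).
3. **Tests** the observed statistic with a two-tailed randomized
   permutation test (`permutation_test()`): virus abundances are permuted
   without replacement while host abundances stay fixed, the statistic is
   recomputed for each of `n_perm` (default $10^4$) independent uniform
   shuffles, and
   $p = \bigl(1 + \#\{|s_{\mathrm{null}}| \ge |s_{\mathrm{obs}}|\}\bigr)
   / (1 + n_{\mathrm{perm}})$.
   The 2.5/50/97.5 percentiles of the null are reported as the randomized
   95% confidence interval.
4. **Corrects** for multiplicity: the Bonferroni threshold is the
   family-wise level divided by the number of tested pairs pooled across
   taxonomic levels (with 64 pairs at family level 0.05 the criterion is
   $0.05/64 \approx 0.00078$), and `tally_significance()` reports per-level
   counts at 0.05, 0.01 and the Bonferroni criterion.

`run_study()` chains these stages, writes TSV reports, the two diagnostic
figures (abundance/VHR scatter with the $-1$ guide line; violin plots of
the permutation nulls with percentile marks and the observed slope in red
dashed) and a run manifest with seed, permutation count, package version
and input checksums.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `min_sites` | 5 | sites | inclusion rule for a testable pair; floor 2 |
| `n_perm` | 10000 | permutations | Monte-Carlo resolution of p (smallest p is $1/(n_{perm}+1)$) |
| `statistic_kind` | `pm_slope` | — | headline estimate is the slope; `pearson_r` is p-value-equivalent under permutation, `spearman_rho`/`theil_sen_slope` are the nonparametric pair |
| `family_alpha` | 0.05 | — | family-wise error rate for Bonferroni |
| `seed` | — | integer | master seed; every pair uses a substream derived from (seed, pair id) |

Because the marginal standard deviations of both log-abundance vectors are
invariant under permutation, the slope and Pearson statistics are strictly
monotone transforms of one another within a permutation stream and yield
identical p-values; the suite asserts this, and the violin figures can be
read interchangeably as slope or correlation nulls.

## The synthetic-data generator

`synthetic_config()` / `generate_collection()` define the ground-truth data
model the whole test harness runs on:

* host log10-abundances are Normal(`host_log_mean` = $-3$,
  `host_log_sd` = 1) — i.e. lognormal relative abundances centred near
  $10^{-3}$ and spanning roughly two orders of magnitude, the standard null
  for abundance data and the spread typical of survey-scale log-log
  abundance plots;
* virus abundances follow $\log_{10} y = \alpha \log_{10} x + c + e$, with
  lognormal noise $e \sim N(0, \sigma_e)$, default $\sigma_e = 0.5$ in
  log10 units — scatter large enough that a 39-site pair under
  independence produces the wide, roughly $-1$-centred VHR slopes the
  diagnostic is about;
* each abundance is independently zeroed with probability `zero_rate`
  (default 0.1) to emulate detection limits; zeros come from random masking
  rather than truncation because what matters downstream is exercising the
  exact joint-positivity filter, not the censoring mechanism;
* defaults `n_sites = 39` and `n_pairs = 64` mirror the survey design the
  pipeline targets (39 sampling sites per pair; 48 genus + 16 phylum
  comparisons).

What the generator does *not* emulate: compositional closure (relative
abundances summing to one, which induces its own negative correlations),
spatial or temporal autocorrelation between sites, and shared sites across
pairs. Passing tests therefore show the machinery is correct under an
idealised lognormal world; they do not show that real relative-abundance
data are free of compositional artefacts.

## Numerical choices

* **log10 throughout.** Slopes are invariant to the logarithm base (tested);
  log10 matches abundance-plot axis conventions.
* **Percentiles** use linear interpolation between order statistics
  (`stats::quantile()` type 7) and this rule is frozen: on the integers
  1..100 the 2.5/50/97.5 percentiles are 3.475, 50.5, 97.525.
* **Add-one p-values** avoid $p = 0$ from finite resampling and make the
  test exact-level for any `n_perm`.
* **Tie handling in the exceedance count.** The vectorised null evaluation
  (one BLAS crossprod per pair) and the scalar observed statistic can
  differ in the last bit, so exceedances are counted with a $10^{-9}$
  relative slack; without it, permutations exactly tied with the observed
  value (at minimum the identity) are dropped erratically and the p-value
  jumps by whole tie-mass units at small $n$.
* **Constant-virus pairs** get $\hat\alpha = 0$ (the flat line is the
  least-squares solution) with $r$ and $\rho$ reported as `NA` — undefined
  rather than fabricated. Under a correlation statistic such pairs are
  *untestable* and appear in the study report with status `"untested"`.
* **Spearman ties** use average ranks; Theil-Sen skips site pairs with
  tied hosts and errors only if every pair is tied.
* **Seeds.** All randomness flows from one master seed through
  deterministic 31-bit substreams keyed by pair id (for permutations and
  generation) or replicate index (for the spurious-slope experiment), so
  results are bitwise reproducible and adding or removing a pair never
  shifts another pair's draws.

## Design decisions taken where the design was open

* The nonparametric slope is **Theil-Sen** and the nonparametric
  correlation is **Spearman**; these are the field-standard choices for a
  "nonparametric slope" and rank correlation, and either can drive the
  permutation test.
* Ratio fits use **ordinary least squares**, consistent with the direct
  fits, so that $\hat\beta = \hat\alpha - 1$ holds as a numerical identity
  check rather than by construction.
* Significance uses the **strict inequality** $p < $ threshold; with
  add-one p-values exact equality is a measure-zero event, so the
  convention is inconsequential in practice but stated for auditability.
* Bonferroni pools **genus and phylum into one family** by default (the
  correction is about the total number of comparisons made); a per-level
  correction is available via `per_level_correction = TRUE`.
* Permutations are independent uniform shuffles, **not guaranteed
  distinct**; at 39 sites duplicate permutations are vanishingly rare and
  the estimator is the standard Monte-Carlo one either way.
* Site sets are allowed to be **ragged across pairs**: each pair's sites
  are validated for uniqueness within the pair only.

## Problem sizes used by the test suite

The suite validates the statistical claims at the sizes the analyses use:
the spurious-slope experiment runs 1000 replicates of 39-site pairs at
noise 0.5; the type-I-error check runs 500 independent null pairs at 2000
permutations each; the small-n oracle check compares 50 Monte-Carlo runs
against full $n!$ enumeration for $n \le 6$; the $\beta = \alpha - 1$
identity is checked on 1000 random datasets at $10^{-10}$ relative
tolerance; and exponent recovery uses 1000-site pairs at
$\alpha \in \{0, 0.5, 1\}$.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  synthetic = synthetic_config(alpha = 0, noise_sd = 0.5, zero_rate = 0.1,
                               n_pairs = 12, n_sites = 39, seed = 42),
  n_perm = 2000, seed = 42, out_dir = "study_out")
res <- run_study(cfg)
res$report
```

Under this independence configuration the per-pair $\hat\beta$ cluster
near $-1$ while only a nominal fraction of pairs reach $p < 0.05$ — the
signature that a wall of $-1$-ish VHR slopes carries no evidence of
virus-host coupling.

## Known limitations

* Relative abundances are analysed as given; compositional corrections are
  out of scope, so genuinely compositional data can still produce spurious
  correlations that the permutation test will faithfully call significant.
* The permutation test assumes exchangeability of sites within a pair;
  spatially structured site effects violate this.
* CIs are percentile intervals of the *null* (randomized CIs), not
  bootstrap intervals of the observed slope.
* FDR-style corrections are not implemented; Bonferroni is the only
  family-wise criterion, as a deliberately strict baseline.
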