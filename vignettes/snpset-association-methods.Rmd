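---
title: "SNP-set association analysis: model, methods and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-set association analysis: model, methods and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `snpsetassoc`, the
parameter choices baked into its defaults, the scope of the synthetic
cohort generator, the numerical decisions worth knowing about, and the
limitations of the whole approach. It states only properties that the
package's test suite actually computes.

## 1. The SNP-set score

A SNP panel is described by a `snp_info()` table in which every SNP has
two alleles and a designated *increaser* allele (the allele associated
with higher trait values). Genotypes are coded additively: 0, 1 or 2
copies of the increaser allele. The SNP-set score of an individual is
the plain, unweighted sum of these codes over the panel
(`build_snpset_scores()`), so a 10-SNP set ranges over 0–20 and a
43-SNP set over 0–86 (`score_bounds()`).

Two missing-data policies are provided:

- `complete_only`: individuals missing any panel genotype get no score.
  Used for small sets, where a single substitution would be a large
  fraction of the signal.
- `mean_substitute` with `max_missing = 3`: a missing genotype is
  replaced by that SNP's mean additive code over all called
  individuals; individuals missing more than 3 panel genotypes are
  marked ineligible. Substitution preserves each SNP's contribution to
  the score *mean* but shrinks its contribution to the score
  *variance*; the suite verifies both effects directly.

Unweighted summation deliberately ignores per-SNP effect sizes. Under
the generator below, the unweighted score correlates ≈ 0.98 with the
optimally weighted genetic path across the default MAF range, so the
resulting attenuation of the estimated correlation is small (and is
covered by the recovery test's ±0.01 bias budget), while the score
stays interpretable as an allele count. `warn_if_ld()` raises an
advisory when panel SNPs are correlated (pairwise r² > 0.2), since the
equal-weight sum implicitly assumes independent markers.

## 2. Genotype quality control

`run_qc()` applies three rules in a fixed order:

1. **Individual/plex call rate.** Genotyping is organized in
   multiplexed batches ("plexes"). If an individual's call rate within
   a plex is below 70%, that whole plex is masked for them (batch
   failure); if every plex fails, the individual is removed.
2. **SNP call rate.** SNPs called in fewer than 95% of individuals are
   removed; exactly 95% is retained. The denominator counts only
   individuals whose plex survived step 1. This matters: with a
   realistic few percent of whole-plex dropouts, charging those masked
   calls against each SNP would push *every* SNP in a plex below 95%
   and delete the panel, even though the assays themselves are fine.
   Batch failure is an individual-level event and is accounted for at
   the individual level.
3. **Hardy–Weinberg equilibrium.** SNPs with exact-test p ≤ 0.01 are
   removed.

The HWE test (`hwe_exact_p()`) is the exact conditional test:
conditional on the allele counts, the probability of a genotype table
with `h` heterozygotes is proportional to
`2^h · n! / (n_AA! · h! · n_aa!)`, and the p-value sums the
probabilities of all tables no more probable than the observed one
(with a 1e-9 tolerance for ties). It is computed with `lgamma` for
stability at n in the thousands and is verified, to 1e-12, against an
independent brute-force enumeration oracle over hundreds of tables.
A chi-square variant is available via `qc_config(hwe_test = "chisq")`.

## 3. Phenotype preparation and association

Measures are standardized (mean 0, SD 1, `n − 1` denominator),
composites are means of available standardized components
(re-standardized; component-availability rules via `composite_spec()`),
and every analysis measure is residualized on sex and its
age-at-testing column and re-standardized (`prepare_measures()`).
Residualize-then-standardize makes all downstream correlations
scale-free and exactly removes the sample correlation with the
covariates.

Association is a one-tailed Pearson test: with estimate `r` over `N`
pairwise-complete pairs, `t = r·sqrt((N − 2)/(1 − r²))` is referred to
the upper tail of the t distribution with `N − 2` degrees of freedom.
The one-tailed choice encodes the directional prior created by coding
genotypes by *increaser* allele: only positive correlations confirm
the nominated direction, and a negative estimate yields p > 0.5 by
construction. Significance is flagged nominally at 0.05 and
Bonferroni-corrected for five tests per measure (per-test alpha 0.01).
`association_table()` reports `r`, per-cell `N`, the p-value and both
flags for every predictor × measure pair, plus a phenotypic
correlation row (`r_p`) of each measure with the focal measure.
`regress_out_and_associate()` re-tests an association after
residualizing the *measure* on one or more control measures
(`partial = TRUE` additionally residualizes the predictor, giving a
true partial correlation).

## 4. Power

`r_to_pct_variance()` and `pct_variance_to_r()` convert between a
correlation and its variance share (100·r²). Power for the correlation
test uses the noncentral t distribution with
`ncp = r·sqrt(n)/sqrt(1 − r²)` (default: one-tailed, alpha 0.05), or a
noncentral chi-square with `ncp = n·r²` and 1 or 2 degrees of freedom.
`detectable_effect()` inverts power in `r` by bisection to 1e-6.

A calibration note: widely used genotypic power calculators evaluate a
2-df chi-square test. The suite confirms that the three classic
80%-power design pairs — (n = 2112, r = 0.067), (n = 1431, r = 0.084),
(n = 3891, r = 0.05) — all sit near 80% power under
`method = "chisq", df = 2` at alpha 0.05, whereas the package's default
one-tailed 1-df test is more powerful (≈ 0.93 at those pairs). When
comparing against published sample-size statements, match the test:
`power_correlation_test(r, n, method = "chisq", df = 2)`.

## 5. The synthetic cohort generator

`simulate_cohort()` is the package's validation instrument; its
defaults (`default_simulation_spec()`) are the study-scale conditions
used throughout the acceptance suite and were fixed before any test
was run.

- **Genotypes.** `n = 4000` unrelated individuals at `k = 43`
  independent SNPs; allele counts are i.i.d. Binomial(2, MAF), so HWE
  holds by construction. MAFs lie on the deterministic grid
  `seq(0.1, 0.5, length.out = k)` — a fixed, reproducible stand-in for
  "common SNPs spanning the usual frequency range" that avoids an
  extra layer of randomness.
- **Effects.** Per-SNP effects are calibrated for equal variance
  contributions: `β_j = target_r / sqrt(k · 2 p_j (1 − p_j))`, so the
  latent genetic path `Z` (standardized weighted allele-count sum)
  explains exactly `target_r²` of a unit-variance focal trait. The
  default `target_r = 0.179` corresponds to a 3.2% variance share.
- **Traits.** Each trait `t` has a *generality* coefficient `rho_t`
  and an optional phenotypic link `λ_t` to the focal trait's residual:
  `y_t = rho_t·target_r·Z + λ_t·ε_focal + sqrt(1 − a² − λ²)·η_t`.
  Thus `rho_t` scales the expected genetic correlation
  (`E[r] = rho_t · target_r`), while `λ_t` produces traits that
  correlate phenotypically with the focal measure yet carry *no*
  genetic signal (`rho = 0`) — the pattern that distinguishes a
  generalist genetic effect from mere phenotypic overlap. The default
  trait set spans `rho ∈ {1, 0.84, 0.79, 0.76, 0.73, 0.62, 0.52, 0}`
  across ages 7–12, with two null motivational measures linked at
  λ = 0.356 and 0.448.
- **Covariates.** Sex (Bernoulli 0.5) shifts each trait by 0.1 SD and
  age (uniform ±0.5 y around the group's testing age) adds a slope of
  0.2 SD/year — deliberately modest nuisance effects that
  `prepare_measures()` must remove before association.
- **Missingness.** Three MCAR mechanisms: whole-plex dropout per
  individual, per-call genotype loss, per-cell phenotype loss. All
  randomness descends from one master seed through three documented
  stage seeds, so cohorts are bit-reproducible.

Setting `target_r = 0` produces a genuinely null cohort (the genetic
path is absent, not merely weak), which the type-I-error acceptance
test exploits.

## 6. Numerical choices

- HWE probabilities in log space (`lgamma`), summed over the
  heterozygote-parity grid; tie tolerance 1e-9.
- `|r| = 1` in the one-tailed test is a boundary: p is 0 (or 1 for
  r = −1) with a warning rather than an error.
- Residualization uses `lm.fit` on complete cases, drops constant
  covariates with a warning, errors on rank deficiency, and errors
  when residual variance falls below 1e-12 of the input variance
  (covariates numerically explaining everything).
- `detectable_effect()` bisects on power to |Δ| < 1e-6.
- All report files are plain text (TSV/CSV/JSON); the run log records
  the seed and a config hash for provenance.

## 7. Limitations

- **No linkage disequilibrium.** SNPs are simulated independently and
  the unweighted score assumes near-independence; correlated panels
  only trigger an advisory.
- **No family structure, selection or stratification.** The generator
  models unrelated individuals from one homogeneous population;
  confounding by ancestry is out of scope.
- **Additivity only.** No dominance, epistasis or gene–environment
  interaction.
- **MCAR missingness.** Real genotyping failures and phenotype
  attrition can be informative; mean substitution is only defensible
  under (approximately) random missingness and small substitution
  counts.
- **One-tailed inference presumes correct allele orientation.** If
  increaser alleles were nominated on noisy evidence, the directional
  prior (and hence the one-tailed test) is optimistic.
- **Scale.** The defaults target cohort sizes in the low thousands and
  panels of tens of SNPs; the package is not engineered for
  genome-wide data.
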