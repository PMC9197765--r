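---
title: "Methods: Mendelian imputation and family-based effect estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian imputation and family-based effect estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `famimpute`, the
numerical and design choices made where several implementations were
defensible, what the built-in simulator does and does not emulate, and the
problem sizes at which the package validates itself.

## The single-locus family model

For sibling `j` in family `i`, with genotypes counting copies of allele "1"
at frequency `f`,

\[
Y_{ij} = \delta g_{ij} + \eta_s g_{ij'} + \alpha_p g_{p(i)} + \alpha_m g_{m(i)}
         + \mu_i + \epsilon_{ij},\qquad
\mu_i \sim N(0, \sigma_F^2),\ \epsilon_{ij} \sim N(0, \sigma_\epsilon^2).
\]

`delta` is the direct genetic effect; `eta_s` the sibling indirect effect;
`alpha_p`, `alpha_m` the parental non-transmitted coefficients (NTCs), which
absorb parental indirect effects plus confounding from stratification and
assortative mating. The population effect estimated by a standard GWAS is
`beta = delta + (alpha_p + alpha_m)/2`. Because offspring genotypes are
randomized by meiosis conditional on parental genotypes, the regression with
(observed or imputed) parental genotypes gives unbiased `delta`.

Two parametrization conventions matter when interpreting coefficients. When
the sibling genotype column is included, the expected coefficients on the
parental genotypes are the *sibling-adjusted* NTCs (`alpha_p - eta_s/2` in
the single-proband parametrization), because a parental allele reaches the
sibling with probability 1/2. The simulator's `alpha_p`/`alpha_m` arguments
are generative coefficients on the parental genotypes with the sibling term
already explicit, i.e. they coincide with the sibling-adjusted NTCs. All
`population_effect()` conversions are written against this bookkeeping:
`beta = delta + alpha` for the parental-sum model without a sibling term,
and `beta = delta + alpha_par + eta_s/2` with one.

## Mendelian imputation

Missing parental genotypes are replaced by exact conditional expectations
given the observed family data. For sibling pairs the conditioning includes
the IBD state; unobserved parental alleles are imputed by `f`:

* IBD0: `g_par_hat = g1 + g2` (all four parental alleles observed);
* IBD1: `g1 + g2_notshared + f`; when both siblings are heterozygous the
  non-shared allele is ambiguous — phased haplotypes resolve it through the
  nearest SNP in the same IBD1 segment at which one sibling is homozygous
  and the other heterozygous, and without phase the two possibilities are
  averaged (`1 + 2f`);
* IBD2: `g1 + 2f`.

The phased sibling-pair imputation has squared correlation 3/4 with the true
parental sum at every allele frequency (per-state contributions 1, 3/4 and
1/2); the best *linear* imputation achieves 2/3. For parent–offspring pairs
the transmitted allele of the missing parent gives R² = 1/2 versus 1/3 for
the linear baseline. Because each imputation is a conditional expectation,
`cov(imputed, truth) = var(imputed)`: regressing the true parental genotype
on the imputed one has slope 1, which is also the diagnostic
(`imputation_diagnostics()`) used on data where held-out parents exist.

Families with three or more genotyped siblings, or siblings plus one parent,
are handled by an exact finite posterior: parental allele slots carry
independent Bernoulli(`f`) priors (conditioned on any observed parent),
inheritance vectors are uniform, and both are constrained by the genotypes
and the pairwise IBD states. This reproduces the pair formulas at `n = 2`
and realizes the `4(1 - 2^-n)` expected observed-allele count. Mutually
inconsistent pairwise IBD states fall back to a genotype-only posterior and
are flagged; Mendelian-inconsistent parent–offspring pairs are imputed as
missing rather than error-corrected, for QC transparency.

**Nonlinearity taxonomy.** Of the `2^4 - 1 = 15` genotype-observation
patterns of a two-offspring family, 7 admit imputations that are nonlinear
in the observed data and therefore add information. The classification
(`classify_nonlinear()`) conditions on the sibling IBD state whenever both
offspring are genotyped, matching what the imputation actually uses. This
choice is load-bearing: at exactly `f = 0.5` the genotype-only conditional
expectation for a sibling pair degenerates to a linear function (a
knife-edge cancellation verified by enumeration), while the IBD-conditional
imputation stays nonlinear at every frequency.

## IBD inference

A hidden Markov model over states {IBD0, IBD1, IBD2} along each chromosome:

* **Emissions.** `P(g1, g2 | IBD = k, f)` from the shared/non-shared allele
  construction (k shared Bernoulli(`f`) draws plus independent ones), with a
  genotyping-error parameter `gamma`: with probability `gamma` an
  individual's genotype is replaced by a Hardy–Weinberg draw. This form was
  chosen for closed-form emissions with full support; missing genotypes
  marginalize out.
* **Transitions.** The state is the sum of two independent binary sharing
  indicators (paternal/maternal). Over `d` cM each indicator flips with
  probability `2θ(1-θ)`, `θ = (1 - e^{-2d/100})/2` (Haldane map; two
  independent meioses per parent). Stationary distribution (1/4, 1/2, 1/4).
* **LD weighting.** Per-SNP emission log-likelihoods are multiplied by the
  inverse LD score, *normalized to mean one per chromosome*. The
  normalization keeps the emission/transition balance invariant to uniform
  LD-score rescaling (so equal LD scores reproduce the unweighted decoder
  exactly) and is used consistently for Viterbi and the forward–backward
  posteriors; the result is an approximate pseudo-likelihood.
* **Decoding and smoothing.** The Viterbi path is authoritative downstream
  (posteriors are reported for QC); ties prefer the state with the larger
  stationary probability (IBD1), then the lower index. Maximal runs shorter
  than `m` cM whose flanks agree are merged iteratively; chromosome-end
  segments are kept. Defaults `(gamma, m) = (1e-4, 0.01 cM)`.

Accuracy scales with marker density per crossover. At roughly 50 SNPs/cM on
a 60 cM chromosome with error rate 1e-4 the per-SNP state accuracy exceeds
99%; residual errors are concentrated in short boundary lags around true
recombination breakpoints and in low-MAF stretches where opposite
homozygotes (the only sharp IBD0/IBD1 discriminator) are rare.

## Estimation

`fit_null_varcomps()` fits `(sigma_F^2, sigma_epsilon^2)` by maximum
likelihood with a 1-D profile over the sibling residual correlation
`r in [0, 0.99]` (`stats::optimize`, tolerance 1e-8); the grand mean and the
total variance are profiled analytically, so each evaluation is O(n), and a
boundary check at `r = 0` guards the degenerate case. SNP effects are then
GLS with the components fixed; `(X'V^{-1}X)^{-1}` is the reported sampling
covariance and is computed through family sums — no dense n×n matrix is ever
formed. The PGI-level model re-estimates the variance components jointly
with the effects (same profile, fixed effects solved inside), since a PGI
can explain non-negligible variance. Genotype columns are centered at the
estimation-sample mean; class-specific NTC columns (parental-sum families
never receive separate father/mother columns) are centered within their
class and zero outside it, which makes the combined multi-class regression
a partitioned model with shared `delta`.

The **robust split estimator** fits each observed-parental-allele group
separately with its own NTC column and combines the `delta` estimates by
inverse variance. Groups in which the imputation is an affine function of
the proband genotype — sibling pairs in IBD2, where
`g_par_hat = g1 + 2f` — carry no direct-effect information and are dropped;
undersized groups (default < 30 families) merge into their nearest
neighbour. With the IBD2 group dropped, the within-state conditional moments
give exactly the `1 + (1-r)/(6(1+r))` efficiency relative to sibling
differences.

**Efficiency baselines.** The closed-form gains are defined against
specific reference estimators, and the replicate experiments implement those
references: for `delta`, the sibling-difference regression; for the average
NTC, the no-imputation GLS of both siblings' phenotypes on (own genotype,
sibling genotype) with `alpha = (3/2) ×` the sibling-genotype coefficient;
for parent–offspring designs, the full trio regression. These
identifications were verified analytically (expected information matrices)
before being frozen into the experiments.

## Moment-based effect-class correlations

For per-SNP estimate pairs `(a_l, b_l)` with known sampling variances and
covariance, the correlation of the underlying true effects is estimated by
corrected central moments:

\[
\hat r = \frac{\widehat{\mathrm{cov}}(a,b) - \overline{s_{ab}}}
{\sqrt{(\widehat{\mathrm{var}}(a) - \overline{s_a^2})
       (\widehat{\mathrm{var}}(b) - \overline{s_b^2})}},
\]

with delete-one block-jackknife standard errors over contiguous,
chromosome-respecting blocks (default 100). Estimates may exceed 1 in noisy
settings and are flagged, not truncated; a non-positive corrected variance
is an error with a diagnostic (the input is noise-dominated). Unweighted by
default, with an optional per-SNP weight column; an optional standard-error
quantile filter is off by default. Cross-sample correlations set the
sampling covariance to zero.

## The simulator

`run_simulation()` iterates mate → meiosis → phenotype and emits the final
generation as nuclear families with two offspring, together with the exact
IBD truth from recorded crossovers. Defaults define the reference
conditions: SNPs in linkage equilibrium at founding with frequencies
Uniform(0.05, 0.5) on a uniform map, one generation, half the variance from
direct effects (`h2_direct = 0.5`) and the rest independent noise.
Assortative mating is noisy phenotype rank matching, calibrated by bisection
on fixed noise draws to the target spousal correlation (±0.02); vertical
transmission adds `vt × (Y_p + Y_m)`; stratification uses Balding–Nichols
deme frequencies with endogamous demes and fixed deme offsets;
ascertainment retains families with probability `plogis(k (pct - c0))` in
the offspring-mean phenotype percentile. The spousal PGI correlation `r_am`
(direct-effect score) and realized `F_st` are recorded.

What the simulator does *not* emulate — and what passing tests therefore do
not certify on real data: local LD from a coalescent history (LD arises only
through assortative mating and drift), genotyping platforms' error
structure (errors are i.i.d. HWE replacements, the same model the HMM
assumes), phasing switch errors (phase is perfect), X chromosomes, selection
and overlapping generations. IBD-HMM accuracy on real data will depend on
map and phasing quality in ways these tests cannot probe.

## Problem sizes used in validation

Chosen once as the package's validation scale: enumeration identities are
exact (tolerance 1e-10). Efficiency ratios use 2,000 replicate experiments
of 20,000 families each (jackknife over replicate blocks; agreement within
3 Monte-Carlo SEs). Bias formulas use 300 replicates of 20,000 (sibling IGE)
or 6,000 (two-deme stratification, `F_st = 0.04`) families.
Standard-error calibration uses 500 replicates of 2,000 trio families, with
the 10% SD/SE band (at 500 replicates the band is ~3 Monte-Carlo SEs wide)
and a Kolmogorov–Smirnov check on pooled z-scores. Correlation recovery uses
50,000 synthetic SNPs, and the end-to-end `r(delta, beta)` scenarios use
1,200–1,400 families × 1,000–1,200 SNPs: a direct-only random-mating trait
(compatible with 1), two-deme stratification (well below 1), and
assortative mating + vertical transmission + parental indirect effects
correlated 0.2 with direct effects. The last choice is deliberate: with a
single phenotype, pure vertical transmission makes per-SNP NTCs nearly
proportional to direct effects, so imperfectly correlated parental IGEs are
what makes `r(delta, beta) < 1` detectable at this scale. IBD validation
uses 100 sibling pairs on a 60 cM chromosome at 50 SNPs/cM.

## Known limitations

* Nuclear families only: no grandparents, avuncular pairs, or reference-
  panel imputation; half-siblings are excluded with a warning.
* The assortative-mating NTC adjustment `(1 + r_am)/(1 + r_am/2)` is derived
  for phased sibling-pair imputation; other classes warn and are returned
  unadjusted.
* The multi-sibling exact posterior enumerates inheritance vectors and is
  limited to five genotyped siblings per family.
* Imputation uses each SNP's own frequency with no multi-SNP conditioning;
  the PGI-level consequences under assortative mating are handled by the
  adjustment above, not in the imputation itself.
* Covariates are expected to be regressed out of the phenotype beforehand.
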