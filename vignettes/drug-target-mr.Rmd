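---
title: "Drug-target Mendelian randomisation with weighted gene-centric scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomisation with weighted gene-centric scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The scientific setting

Variants in a gene encoding a drug target perturb the target's activity from
conception, so their downstream associations anticipate the on-target
effects of pharmacological inhibition. `targetmr` implements this design for
an LDL-lowering target (the PCSK9 setting is the shipped default): four
approximately independent variants in one locus act as instruments for LDL
cholesterol, and the question is what a 1 mmol/L lower LDL, achieved through
this locus, does to glycaemic and anthropometric traits and to type 2
diabetes risk.

The inference has two levels. Per-SNP, per-study additive regressions are
pooled across studies by inverse-variance weighting (IVW); each SNP's pooled
outcome effect is then rescaled by that SNP's own pooled LDL effect (a Wald
ratio) onto a per-1-mmol/L-lower-LDL basis; finally the scaled estimates
are pooled across SNPs into a weighted gene-centric score (GS). Because
replication data at the half-million-participant scale cannot be shipped,
the package pairs the analysis machinery with a calibrated synthetic-data
generator whose true effects are set to the published point estimates, so
every stage is testable by parameter recovery.

## The causal model and estimand

For individual $i$ in study $s$ with minor-allele dosages
$g_{ij} \in \{0,1,2\}$ (the counted allele is always the LDL-lowering one):

$$\mathrm{LDL}_i = \mu_0 + \textstyle\sum_j \beta_j^{\mathrm{struct}} g_{ij} + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma_L^2)$$

Every outcome responds only to the realised LDL deficit
$d_i = \mu_0 - \mathrm{LDL}_i$ (full mediation — the MR identifying
assumption; a pleiotropy knob exists but defaults to off):

* continuous trait: $y_i = \alpha + \theta\, d_i + e_i$;
* diabetes: $\Pr(\text{case}) = \operatorname{logit}^{-1}(\alpha_D + \theta_D\, d_i)$.

$\theta$ (or $\theta_D$, a log-odds) is the estimand: the effect of 1 mmol/L
*lower* LDL. Harmful metabolic effects therefore appear as positive numbers,
and for every SNP the true marginal per-allele outcome effect equals
$\theta \, |\beta_j|$, so the Wald ratio recovers $\theta$ regardless of
which SNP carries it.

### Marginal versus structural LDL effects

Published per-allele LDL effects are *univariable* (marginal) estimates.
Under residual LD a marginal effect absorbs contamination from correlated
causal variants, so the generator treats each variant's `beta_ldl` as the
target marginal effect and solves the structural coefficients from the
dosage covariance, $\beta^{\mathrm{struct}} = C^{-1}(v \circ m)$
(`structural_betas()`). With independent variants the two coincide. This is
what makes the pipeline's univariable output land on the published values
(−0.02 and −0.34 mmol/L for the smallest- and largest-effect variants) while
the multivariable model recovers the conditional coefficients.

## The synthetic world

**Genotypes.** Each SNP's dosage comes from double-thresholding one latent
standard normal at its Hardy-Weinberg cut points; cross-SNP dependence is a
Gaussian copula whose latent correlation is solved numerically (1-D
quadrature plus root finding) so the realised dosage $r^2$ hits its target.
This supports arbitrary MAF combinations without haplotype bookkeeping. The
attainable $r^2$ is bounded for unequal MAFs; requests beyond the bound are
refused with the bound reported, and a generation-time check compares
realised $r^2$ against it. An inbreeding coefficient $F$ per study shifts
the thresholds to a heterozygote deficit $2pq(1-F)$, which is how
HWE-violating studies are injected.

**Default panel and LD.** MAFs 0.14, 0.01, 0.36, 0.17 with marginal LDL
effects −0.02, −0.34, −0.06, −0.10 mmol/L (the first two published in text;
the last two plausible placeholders, not treated as published values). The
default LD matrix has a single correlated common pair at the maximum
residual $r^2$ of 0.26 and independence elsewhere: with additional LD the
smallest-effect variant's marginal effect would be entirely LD-explained,
making it conditionally null and contradicting the premise that LD
correction leaves results similar.

**Traits and calibration.** Defaults per 1 mmol/L lower LDL: fasting
glucose +0.09 mmol/L (baseline 5.38, residual SD 0.8), HbA1c +0.03%
(5.50, 0.55), log fasting insulin 0 (insulin is simulated on the natural-log
scale because percent differences are only coherent for a log-transformed
analyte), bodyweight +1.03 kg (78, 15), height +0.008 m (1.70, 0.095),
waist-to-hip ratio +0.006 (0.87, 0.07), diabetes log-odds ln(1.29) with
baseline log-odds −2.30 (prevalence ≈ 9.1%, half of cases flagged
prevalent). BMI is *not* simulated: it is computed as weight/height², which
reproduces the attenuation of the BMI effect relative to bodyweight when
height also responds. LDL residual SD is 0.9 mmol/L (a typical
individual-level SD); the zero-dosage baseline 3.4699 mmol/L is chosen so
the marginal population mean is 3.41 mmol/L. 70% of individuals carry
fasting measures; glucose and insulin models use only those. Missingness is
available (MCAR per variable) but defaults to 0. The default scale is 20
studies of 10 000 — large enough for recovery tests at desk runtime, ~35×
smaller than the real consortium sample.

**What the generator does not emulate** (so what a green test does not
establish): population structure and ancestry confounding, genotyping error,
imputation dosages, covariate structure (age, sex), survival time for
incident diabetes, between-study heterogeneity in true effects, and
selection effects such as lipid-lowering treatment. Consortium records are
drawn directly from the estimator's large-sample sampling distribution
(`emit_consortium_summary()`), not from simulated individuals.

## The analysis pipeline

**Per-study fits** (`associate_study()`): crude additive regressions
(dosage 0/1/2), linear for continuous traits by closed-form OLS, logistic
for diabetes by IRLS with a complete-separation guard (|beta| > 15 errors)
and available-case missing-data handling. No covariate adjustment, matching
a common analysis script that is not described as adjusting. Quality
machinery per study: a 1-df Hardy-Weinberg chi-square per SNP; an
additivity likelihood-ratio test (additive vs genotypic factor model, 1 df);
a multivariable model with all four SNPs; and a sparse-cell guard flagging
binary fits with any non-empty genotype-by-outcome cell below 5 (the rare
variant in small studies), excluded from pooling by default.

**Pooling** (`pool_all()`): (study, SNP) pairs failing HWE at p < 1e-6 (a
conventional GWAS threshold; the published analysis names no numeric value)
are excluded from all traits with a logged rule. Consortium summary records
enter alongside study estimates through an explicit overlap map naming the
studies each consortium subsumes — double counting is resolved by declared
provenance, never inferred. Fixed-effect IVW ($w_i = 1/\mathrm{se}_i^2$) and
DerSimonian–Laird random effects are both reported everywhere, with
Cochran's Q, $I^2 = \max(0, (Q-(k-1))/Q)$, and a one-sided upper 97.5%
bound on $I^2$ from the test-based interval on $\ln H$.

**Scaling and the score** (`run_trait_analysis()`): the order is fixed —
pool across studies, scale each SNP by its *own* pooled LDL effect, pool
across SNPs. Variance scaling uses the squared multiplicative inverse
(se/|β|): the first-order delta-method result; multiplying a variance by an
unsquared inverse is dimensionally incoherent. The LDL denominator is
treated as fixed (no second-order term). SNPs whose pooled LDL effect falls
below a configurable weak-instrument floor (default 0.005 mmol/L) are
dropped from the score with a record.

## Sensitivity analyses

* **Additivity**: per-study LRT p-values are Fisher-combined per SNP
  ($X = -2\sum \ln p_i$, chi-square on $2k$ df).
* **LD correction**: univariable and multivariable routes are compared on
  the *causal* (per-mmol) scale, each scaled by its own LDL estimate. On
  the per-allele scale marginal and conditional coefficients differ
  mechanically whenever LD and multiple causal variants coexist; under
  mediation that contamination cancels in the Wald ratio, so similarity on
  the causal scale is the meaningful invariance.
* **Incident/prevalent split**: the pipeline reruns with cases restricted
  to one stratum, keeping all non-cases as the comparison group (controls
  are not split).
* **Dose-response**: inverse-variance-weighted correlation and WLS
  regression of per-allele diabetes log-odds on the magnitude of per-allele
  LDL lowering, weights $1/\mathrm{var}(\log \mathrm{OR})$, with
  leave-one-SNP-out recomputation; the slope p-value uses $k-2$ error df —
  a convention choice, since the original figure does not state its method.

## Numerical choices

* All CIs use the normal critical value 1.959964; no small-sample t
  adjustment (large-sample GWAS practice).
* Logistic convergence: IRLS epsilon 1e-10, max 50 iterations; SEs from the
  inverse observed information.
* Fisher's method clips p = 0 to the smallest positive double with a
  warning.
* Tabular output is serialised at 6 significant digits, round-half-even, so
  golden files are portable; rerunning a configuration reproduces outputs
  byte for byte.
* One global seed expands into per-stage, per-study substreams via a fixed
  affine counter scheme modulo a Mersenne prime (`substream_seed()`), so
  adding a study never perturbs another study's draws.
* The latent copula correlations are solved once per (MAF, LD) set and
  cached; the solver refuses non-PSD latent matrices, reporting the
  offending eigenvalue.

## Known limitations

* **Independence approximation of the GS.** With the default residual LD
  (dosage correlation ≈ 0.51 for one pair), the scaled per-SNP estimates
  are correlated and IVW-with-independence understates GS variance by
  ~1.4×, giving ≈ 90% empirical coverage for a nominal 95% CI. This is a
  property of treating "approximately independent" SNPs as independent —
  shared with the original design — and is why the CI-calibration test runs
  on an independent-SNP world (where coverage is ≈ 94%).
* **Weak instruments at small n.** Wald ratios for the smallest-effect
  variant are unstable below ~50 000 total individuals; the floor drops
  such SNPs rather than propagating unstable ratios, and small worlds show
  visible upward noise in the diabetes score.
* The log-OR/SE correlation inherent to logistic fits slightly tilts IVW
  weights in very small studies; at the default study size the diabetes GS
  is empirically unbiased (mean OR 1.294 over 30 replicates).
* Only the DerSimonian–Laird random-effects estimator is implemented, and
  no MR-Egger/median/mode pleiotropy-robust estimators: the mediation
  assumption is imposed by the generator, not tested by the pipeline.

## A small worked run

```{r example}
cfg <- sim_config(n_studies = 3, n_per_study = 2000, seed = 7)
res <- run_full(run_config(simulation = cfg, log_level = "quiet"))
gs <- res$forest[res$forest$level == "GS_fixed",
                 c("trait", "beta", "se", "ci_low", "ci_high", "or")]
gs
```

At this deliberately small scale the intervals are wide; the acceptance
suite (`tests/testthat/test-acceptance.R`) runs the default 20 × 10 000
world and checks recovery of every calibrated truth within three
Monte-Carlo standard errors, plus the closed-form and calibration oracles.
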