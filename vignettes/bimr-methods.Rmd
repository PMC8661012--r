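---
title: "Methods: bi-directional one-sample Mendelian randomization with bimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bi-directional one-sample Mendelian randomization with bimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(bimr)
library(dplyr)
```

## The problem

Observational cohorts routinely show an association between platelet count
and hypertension, but a crude regression cannot say whether elevated platelet
counts raise the risk of hypertension, whether hypertension alters platelet
counts, or whether shared confounders (age, sex, metabolic and hematological
traits) drive both. Mendelian randomization (MR) addresses this by using
genetic variants as instrumental variables: alleles are assorted at meiosis
independently of later-life confounders, so a variant that changes the
exposure provides a natural experiment on the outcome. `bimr` implements the
full one-sample, bi-directional workflow — genotype quality control,
instrument discovery by association scan, weak-instrument screening, and the
standard summary-statistic causal estimators — together with a synthetic
cohort generator and a Monte-Carlo harness that measure how the estimators
behave when the causal structure is known.

An instrument $G_j$ must satisfy three assumptions: *relevance* ($G_j$
predicts the exposure $X$), *independence* ($G_j$ is independent of
confounders of the $X$–$Y$ association), and *exclusion restriction* ($G_j$
affects the outcome $Y$ only through $X$). Only the first is empirically
testable; the estimators below differ in how they behave when the third
fails (pleiotropy).

## Generative model of the synthetic cohorts

`simulate_cohort()` draws cohorts with exactly the structure the analysis
assumes, so every pipeline stage is testable without access-restricted
biobank data. Genotypes are biallelic dosages $g_{ij} \sim
\mathrm{Binomial}(2, p_j)$ — Hardy–Weinberg proportions by construction.
In the forward generative mode,

$$X_i = \textstyle\sum_j \beta_{Xj} g_{ij} + \gamma^\top C_i + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma_X^2),$$

$$Y_i \sim \mathrm{Bernoulli}\!\left(\mathrm{logit}^{-1}\!\big(c + \theta X_i
 + \textstyle\sum_j \alpha_j g_{ij} + \textstyle\sum_k b_k g_{ik}
 + \delta^\top C_i\big)\right),$$

where $\theta$ is the causal effect of interest, $\alpha_j$ are direct
(pleiotropic) effects of the exposure instruments, $b_k$ are effects of a
disjoint outcome-instrument block (these become the instruments of the
reverse analysis), and $C_i$ are confounders drawn independently of
genotype, so the independence assumption holds by construction. A
continuous-outcome variant replaces the logistic link with a linear model
plus Gaussian noise. The reverse mode generates the binary trait first from
its own instruments and adds `reverse_effect` times the binary trait to the
continuous one; pleiotropy then attaches to the block of whichever trait is
generated first.

The binary trait is generated directly through the logistic link rather
than by thresholding a simulated blood-pressure liability: the causal
estimand is stated on the log-odds scale (results are reported as odds
ratios), and a liability-threshold layer would add a parameter the
estimators cannot see. One consequence is *non-collapsibility*: with a
binary outcome the population quantity the ratio estimates converge to is an
attenuated conditional log-odds ratio, not the generative $\theta$. Tests of
binary-outcome behaviour therefore compare estimators against a two-stage
least squares oracle computed on the same individual-level data (`tsls()`),
never against raw $\theta$.

Default confounder marginals (`default_confounders()`) mimic a middle-aged
East-Asian biobank panel — age $\sim N(48.7, 11^2)$, sex
$\sim\mathrm{Bernoulli}(0.498)$, plus seven clinical covariates — but the
marginals are cosmetic; only the effect vectors on the two traits are
load-bearing, and they default to zero.

One root seed drives everything. Each stage (MAF draw, genotypes,
confounders, traits, missingness, bootstrap) derives its own stream from
the root by a fixed label scheme, so identical configuration plus seed
reproduces a cohort, and a full pipeline run, bit for bit.

What the generator does **not** emulate: linkage disequilibrium between
instruments (the estimators assume uncorrelated instruments; a Gaussian
copula block generator, `simulate_ld_block()`, exists solely to exercise the
LD pruner), population stratification, relatedness, genotyping batch
effects, and measurement error in the traits. Passing tests therefore show
the estimators behave correctly under their stated assumptions, not that
those assumptions hold in any particular biobank.

## Quality control

`qc_pipeline()` applies the conventional cascade in the conventional order,
with every removal recorded once under the first stage that triggered it:

1. **Individual missingness** — drop individuals with missing-call fraction
   strictly above 5%.
2. **SNP call rate** — drop SNPs with call rate strictly below 97%,
   computed over the retained individuals.
3. **Hardy–Weinberg equilibrium** — drop SNPs whose exact-test p-value
   falls below `hwe_alpha`. The threshold default is $10^{-6}$, common GWAS
   practice; it is a configurable parameter and nothing downstream depends
   on the default.
4. **LD pruning** — within a sliding window (50 SNPs, step 5, both
   configurable; `window_snps = Inf` gives the all-pairs scan), drop the
   later-positioned member of any pair with squared dosage correlation
   strictly above 0.8.

The Hardy–Weinberg test is the conditional exact test: given the observed
allele counts, the heterozygote count under equilibrium has distribution
$P(h) \propto n!\,2^h / (n_{AA}!\,h!\,n_{BB}!)$, and the two-sided p-value
sums the probabilities of all configurations no more probable than the one
observed. The exact test was chosen over the chi-square approximation
because QC fixtures (and real rare variants) involve small genotype counts
where the approximation fails; it is computed by a numerically stable ratio
recurrence, is necessarily conservative (super-uniform under the null), and
a mid-p variant is available but off by default.

$r^2$ is the squared Pearson correlation of additive dosages over
pairwise-complete observations (composite LD). It is deterministic and
phase-free; comparisons with PLINK should use PLINK's matching
dosage-correlation mode, not EM-phased haplotype $r^2$. The pruning
tie-break — drop the later-positioned SNP — is deterministic and
index-stable.

## Association scans and instrument selection

`gwas()` fits one regression per SNP — trait on dosage plus covariates —
linear for continuous traits, logistic (IRLS, maximum 25 iterations,
deviance tolerance $10^{-8}$, Wald normal p-values) for binary ones, using
complete cases per SNP rather than global row deletion, and flagging
monomorphic SNPs as not testable. When the genotype block is complete, the
linear scan uses a residualize-then-regress shortcut that is algebraically
identical to the per-SNP multiple regression.

Instrument selection applies a strict `p < 5e-6` threshold (configurable);
screening then computes each candidate's partial F-statistic against the
exposure after covariates,
$F = (RSS_0 - RSS_1)/(RSS_1/(n - p_1)) = t^2$, and retains candidates with
$F \ge 10$ inclusive, the conventional weak-instrument rule. The partial F
is per-SNP; a joint F across instruments would answer a different question
(the variance explained by the set) and is not what the screen needs.
Instruments are selected and used in the *same* cohort — the one-sample
design — which is faithful to how such studies are run; the winner's-curse
consequences are quantified, not hidden (below).

The effect allele is whichever allele the dosage counts; `harmonize()` joins
exposure and outcome statistics on shared SNPs, verifies allele annotation,
and orients every pair so $\hat\beta_{Xj} \ge 0$ (flipping
$\hat\beta_{Yj}$ in tandem), which leaves all estimators invariant.

## Causal estimators

With per-instrument summary statistics $(\hat\beta_{Xj}, \hat\beta_{Yj},
se(\hat\beta_{Yj}))$, the per-instrument ratio estimate is $\hat\theta_j =
\hat\beta_{Yj}/\hat\beta_{Xj}$, with delta-method standard error
$se(\hat\beta_{Yj})/|\hat\beta_{Xj}|$.

**IVW.** The inverse-variance-weighted estimate

$$\hat\theta_{IVW} =
\frac{\sum_j \hat\beta_{Yj}\hat\beta_{Xj}/se(\hat\beta_{Yj})^2}
     {\sum_j \hat\beta_{Xj}^2/se(\hat\beta_{Yj})^2}$$

is weighted least squares of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through
the origin. The fixed-effect model (default) uses
$se = (\sum_j \hat\beta_{Xj}^2/se(\hat\beta_{Yj})^2)^{-1/2}$; the
multiplicative random-effects option inflates this by $\max(1,\hat\sigma)$,
$\hat\sigma^2$ being the weighted residual mean square — never deflating,
so overdispersion widens intervals and underdispersion is ignored. Both are
implemented because published tables rarely label which was used; results
carry a `model` column naming the choice.

**MR-Egger.** The same weighted regression with a free intercept. The slope
estimates the causal effect under InSIDE (pleiotropic effects distributed
independently of instrument strength); the intercept estimates average
directional pleiotropy, and its test is the standard diagnostic for bias in
IVW. The residual variance factor is floored at 1, per standard MR-Egger
practice, so Egger intervals are never narrower than the fixed-effect ones.
Egger needs at least three instruments and loses precision when the
$\hat\beta_{Xj}$ are similar in magnitude (the intercept and slope become
collinear).

**Simple and weighted median.** Order the ratio estimates; form cumulative
standardized weights $p_j = (S_j - w_j/2)/S_{total}$ (equal weights for the
simple median, inverse delta-method ratio variances
$\hat\beta_{Xj}^2/se(\hat\beta_{Yj})^2$ for the weighted median); linearly
interpolate the ratio at cumulative weight 0.5. The simple median is
consistent when at least half the instruments are valid; the weighted
median when valid instruments carry more than half the weight. Standard
errors come from a seeded parametric bootstrap — per instrument, resample
both effect estimates from $N(\hat\beta, se)$, recompute the estimator,
take the standard deviation over `n_boot` draws (default 2000) — and
p-values from the normal approximation with the bootstrap SE.

Throughout, confidence intervals are $\hat\theta \pm 1.959964\,se$ and
p-values are two-sided normal. The normal (rather than $t$) reference is a
deliberate package-wide convention matching how such results are reported;
its practical consequence is that the Egger intercept test attains its
nominal size only for moderately many instruments (the package's
calibration check uses 25), and is mildly anticonservative for very small
instrument sets. Binary-outcome estimates are log-odds ratios per exposure
unit; `to_odds_ratio()` exponentiates estimate and interval.

In the reverse direction the exposure is binary, so $\hat\beta_{Xj}$ sits
on the log-odds scale and the causal estimate is "continuous-trait units
per log-odds of exposure liability" — an awkward but standard estimand for
binary exposures; the package reproduces it as-is and documents rather than
reinterprets it.

## The bi-directional pipeline

`run_direction()` chains scan → select → screen → outcome scan → harmonize
→ estimate, persisting every intermediate; `run_bidirectional()` runs both
directions plus the crude covariate-adjusted regressions (logistic
binary-on-continuous and linear continuous-on-binary) that quantify the
observational association the MR interrogates. Covariate adjustment is
applied in both the exposure and outcome scans with the same configured
set. A direction with no surviving instruments reports its status without
affecting the other. `render_report()` serializes the study as lossless
JSON, TSV, or a markdown table (three decimals by default) with one block
per direction and the Egger intercept as its own row.

## The simulation study and its registered scenarios

`simulation_study()` replicates registered scenarios and reports, per
estimator: mean estimate, bias, empirical SE, mean model SE, 95% CI
coverage, and rejection rate at 0.05. Replicate-level results are kept for
audit. The registered scenarios, with the problem sizes used by the
package's own validation runs:

* `valid_ivs` — $n = 10{,}000$, five independent instruments with
  per-allele effects 0.15–0.25 exposure-SD and MAFs 0.2–0.4 (per-SNP
  $F \approx 100$–$200$), continuous outcome, $\theta = 0.2$. Used for
  parameter recovery and coverage (200 replicates) and, with $\theta = 0$
  at $n = 5{,}000$, for type-I error (1000 replicates).
* `balanced_pleiotropy` — ten instruments, $\alpha_j \sim N(0, 0.05)$:
  InSIDE holds with zero mean, IVW remains consistent.
* `directional_pleiotropy_inside` — $\alpha_j \sim N(0.08, 0.02)$ drawn
  independently of instrument strength. The mean 0.08 was set from the
  designed Egger-intercept standard error ($\approx 0.025$ at these sizes)
  to give the intercept test roughly 0.9 power. With
  `invalid_frac < 1`, a random minority of instruments instead receives a
  fixed offset — the setting where the weighted median is consistent and
  IVW is not.
* `weak_instruments` — five instruments with $F$ far below 10, documenting
  why the screen exists.
* `reverse_causation` — data generated with the binary trait causal
  ($\theta_{rev} = 0.8$) and the forward analysis run against it: the
  forward IVW stays null because the exposure instruments carry no path to
  the outcome.
* `winner_curse_split_compare` — twenty modest instruments
  ($\beta_X = 0.085$, $n = 6{,}000$, selection at $p < 10^{-3}$) and an
  *unobserved* confounder affecting both traits. The confounder is
  essential: with valid instruments and independent noise, one-sample IVW
  is conditionally unbiased under selection
  ($E[\hat\beta_{Yj}\mid\hat\beta_{Xj}] = \theta\hat\beta_{Xj}$), so
  winner's curse only materializes when the two scans' errors correlate.
  Selecting in the estimation sample then drags the estimate toward the
  confounded observational association; selecting in an independent half
  removes the bias at the cost of power. The scenario reports both.

Scenario parameters are part of the scenario definitions; the harness
accepts overrides so null and variant runs reuse the same machinery.

## Numerical choices and degenerate inputs

* HWE exact probabilities by ratio recurrence with periodic rescaling;
  monomorphic SNPs return p = 1 (single attainable configuration).
* Logistic separation (the model classifies every case with certainty)
  raises an error; IRLS non-convergence is flagged in the result status,
  never silent.
* Zero exposure effects cannot be oriented and are rejected before
  estimation (screening precludes them in practice).
* Ties in the median interpolation are resolved by ordered cumulative
  weights; a single instrument collapses IVW to the ratio estimate, and a
  random-effects request with one instrument falls back to fixed with a
  warning.
* The Egger fit refuses all-identical exposure effects (the design is
  singular).

## Limitations

The package validates estimator behaviour under its own generative model.
It does not model LD between instruments (beyond the pruner's test
fixture), population structure, assortative mating, selection into the
cohort, or time-varying exposures — all of which can bias real MR studies
in ways no amount of synthetic validation here will detect. The
binary-outcome estimand is non-collapsible, so estimates from cohorts with
different covariate sets are not directly comparable. And the one-sample
design's winner's curse is reported, not corrected: the split-sample mode
quantifies it in simulation but the headline pipeline remains faithful to
the single-cohort design.

## A small worked run

```{r worked, fig.width = 6, fig.height = 4}
cfg <- sim_config(
  n_individuals = 4000,
  instrument_effects = c(0.20, 0.15, 0.25, 0.18, 0.22),
  outcome_instrument_effects = rep(0.25, 5),
  maf = c(0.2, 0.25, 0.3, 0.35, 0.4, rep(0.3, 5)),
  causal_effect = 0.5, seed = 7)
cohort <- simulate_cohort(cfg)

g <- qc_pipeline(cohort$genotypes)
report <- run_bidirectional(g, cohort$phenotypes, "exposure", "outcome",
                            p_threshold = 1e-4, seed = 7)
tidy(report)
autoplot(report$forward$results)
```
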