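---
title: "Evaluating polygenic scores for a rare disorder under the liability threshold model"
author: "pgsEval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating polygenic scores under the liability threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsEval)
```

# The problem

Polygenic scores (PGS) summarise common-variant liability to a trait as a
weighted sum of allele dosages. For a rare disorder such as cerebral palsy
(population prevalence on the order of 1 in 300 to 1 in 700),
case-control cohorts are heavily ascertained: cases are oversampled by two
orders of magnitude relative to their population frequency. Every
observed-scale association measure — odds ratios, AUC, regression
R² — is inflated or distorted by that ascertainment, and comparing
variance explained across cohorts with different prevalences or
case:control ratios requires mapping everything onto a common scale: the
latent *liability* scale.

pgsEval packages the full evaluation battery for this setting: allelic
scoring against per-variant weight tables, kinship-based relatedness
pruning, age matching, ancestry principal components, and per-trait
association / discrimination / liability-variance statistics. Because real
genotype cohorts for rare disorders are access-controlled, the package
also contains a first-class synthetic cohort generator under an additive
liability-threshold model, so that every stage — including the
ascertainment correction itself — can be verified against known truth.

# The liability threshold model

A standard-normal latent liability $L = g + e$ is split into a genetic
score $g$ (variance $h^2$) and independent noise. An individual is
affected iff $L > t$ with $t = \Phi^{-1}(1-K)$, $K$ the population
prevalence. Under this model the Lee transformation converts an
observed-scale incremental $R^2_{obs}$ (binary outcome regressed on the
score, full minus covariate-only model) into liability-scale variance
explained:

$$
z = \varphi(t),\quad m = z/K,\quad
C = \frac{K(1-K)}{z^2}\,\frac{K(1-K)}{P(1-P)},\quad
\theta = m\,\frac{P-K}{1-K}\left(m\,\frac{P-K}{1-K} - t\right)
$$

$$
R^2_l = \frac{R^2_{obs}\, C}{1 + R^2_{obs}\,\theta\, C}
$$

where $P$ is the case proportion *in the analysis sample* (recomputed
after pruning and matching, and inside every bootstrap resample). Two
checkable consequences anchor the implementation: at $K = P$ the
correction is the pure scale factor $C$ ($\theta = 0$), equal to $\pi/2$
at $K = P = 0.5$; and $R^2_{obs} = 0$ maps to $R^2_l = 0$ for any
$(K, P)$. The package's tests also verify the transformation's purpose
empirically: resampling one generative model at 1:1 versus 1:40
case:control leaves mean $R^2_l$ within 10% while mean $R^2_{obs}$ moves
more than two-fold.

# The statistical battery

For each trait and for the combined predictor, `evaluateCohort()` reports
three families:

* **Association**: logistic regression of case status on the
  cohort-standardised PGS, adjusted for sex and 10 ancestry PCs, as eight
  single-PGS models plus one multiple-PGS model; odds ratios per SD with
  95% Wald CIs, Benjamini-Hochberg adjustment over 8 comparisons within
  each model family.
* **Discrimination**: Mann-Whitney AUC (ties counted 0.5) with the
  Hanley-McNeil standard error, one-tailed $Z = (AUC - 0.5)/SE$, 90%
  one-sided lower bound $AUC - 1.6449\,SE$, B-H over 9 comparisons
  (8 single + combined).
* **Liability variance**: $R^2_{obs}$ as the full-minus-reduced linear
  model difference, transformed as above; 1000 individual-level bootstrap
  resamples give the SE (SD of resampled $R^2_l$), the 90% one-sided
  lower bound (5th percentile) and a one-tailed $Z = R^2_l/SE$ test; B-H
  over 9.

Design choices where the procedure was genuinely open:

* **Combined ROC predictor.** The combined AUC uses the linear predictor
  of a PGS-only logistic model; whether covariates belong in the ROC
  model is ambiguous, so a covariate-adjusted variant is available via
  `rocAdjusted = TRUE`.
* **SE for the Z tests.** Hanley-McNeil for AUC; bootstrap SD for
  $R^2_l$. Neither choice has a canonical alternative that is both
  assumption-free and closed-form.
* **Nonnegativity of the liability test.** Incremental $R^2_{obs}$ from
  nested least squares is nonnegative by construction, so the point
  estimate never needs clipping and the one-tailed bootstrap-Z test is
  conservative under the null: its type-I error sits far below the
  nominal 5% (the package's calibration tests measure roughly 0.1% at
  the 322/1610 design) while the AUC test calibrates at the nominal
  rate. Users should read non-significant liability-variance tests
  accordingly.
* **B-H family sizes** follow the stated comparison counts (8 for the
  regression families, 9 for AUC and $R^2_l$); when a user supplies a
  different trait count the family grows to match, never shrinks.

Descriptive helpers (`chiSquare2x2` with Yates correction,
`welchTFromSummary` with Satterthwaite df, `effectiveSampleSize` =
$4/(1/n_{cases} + 1/n_{controls})$) reproduce standard cohort-table
statistics from printed counts and summary statistics alone. Note that a
Welch statistic recomputed from *rounded* summaries will differ slightly
from one computed on raw data; the helper reproduces the method, not
unrounded inputs.

# Scoring and harmonisation

`computeScores()` implements plain allelic scoring: raw score
$= \sum_m w_m \, d_m$ with $d_m$ the effect-allele dosage. Weight rows are
matched to cohort variants by id; an effect allele equal to the VCF ALT
uses the dosage as-is, equal to REF flips to $2-d$, and any other allele
pair is skipped with an audit reason (`allele_mismatch` /
`missing_variant`). No strand flipping is attempted: silent A/T-C/G
guessing is a known error source, and in the synthetic setting both files
are under package control. Missing dosages are mean-imputed as
$2 f_{effect}$ by default (`"omit"` with per-sample renormalisation is
available); the missing-genotype policy at scoring time is a convention,
not a derivable fact. Scores are z-scored within the analysis cohort with
the population-SD denominator $n$ — any positive affine transform of the
raw score leaves every downstream statistic unchanged, so the choice of
sum versus average and of denominator is inconsequential and made for
simplicity.

# Relatedness and matching

Kinship is estimated from the genetic relationship matrix,
$\hat\phi_{ij} = \frac{1}{2M}\sum_m
\frac{(x_{im}-2p_m)(x_{jm}-2p_m)}{2p_m(1-p_m)}$, with frequencies from
the cohort itself and per-pair non-missing overlap in the denominator.
Expected values are 0.5 for duplicates and 0.25 for first-degree pairs;
the default pruning threshold 0.09 captures second-degree and closer.
Estimation noise scales as $M^{-1/2}$ and the estimator carries a small
finite-sample bias of order $-1/n$ from estimating the frequencies in
the cohort; at the package's defaults (2000+ variants, hundreds of
samples) both are far inside the threshold.

Pruning removes one individual per related pair while *retaining the
maximally sized cohort*: that is a minimum-vertex-cover problem on the
relatedness graph, solved exactly by enumeration on components of up to
12 vertices and by greedy max-degree removal on larger ones. Among
equally small covers the one removing more controls is preferred, then
the lexicographically smallest id set, making results deterministic.

Matching (`matchControls()`) is greedy nearest-neighbour without
replacement at a configurable ratio (default 1:5) on age or any covariate
list; cases are processed in a seeded random order because greedy results
depend on order and no canonical order exists. Distance ties break to the
smaller control id. `balanceDiagnostics()` reports standardized mean
differences before and after. Balance after matching is only achievable
when the control pool covers the case covariate range — with cases
averaging 9 years and controls 61, matching cannot fix the imbalance and
the youngest-*n*-controls restriction (`youngest_controls` in the run
config) is the appropriate sensitivity design instead.

# The synthetic cohort generator

The generator is the package's test harness and its defaults *are* the
emulated study conditions for the smaller cohort: prevalence
$K = 0.0032$, 322 cases and 1610 controls ascertained from a pool of
150,000; two subpopulations with Balding-Nichols divergence
$F_{st} = 0.01$ (subpopulation frequencies Beta-distributed around an
ancestral frequency with variance $F_{st}\,p(1-p)$, Hardy-Weinberg
within subpopulation, variants independent); case ages
$\mathcal{N}(8.9, 5.1^2)$ versus control ages $\mathcal{N}(61.2, 9.6^2)$
truncated at 0; female fractions 0.40 (cases) and 0.576 (controls);
genotype missingness 0.002; and ten injected related pairs (2 duplicate,
4 parent-offspring, 4 full-sib) built by explicit gamete transmission.
A `cohort = "australia"` preset switches to $K = 0.0014$ with
525 / 20,410.

Eight traits mirror a cerebral-palsy PGS panel. Per-variant true effects
are drawn from a single-factor Gaussian model: each trait's effects
correlate $\rho$ with the disorder-liability trait and $\rho_i\rho_j$
with each other, which keeps the implied correlation matrix positive
semi-definite for any $|\rho| \le 1$ (it is checked regardless). Effects
are rescaled so each trait's genetic score has variance $h^2$
(default 0.3). Estimated weights add Gaussian noise with variance
$1/(2p(1-p)\,n_{eff})$ — the GWAS sampling variance of a per-allele
effect for a standardised trait — so the discovery effective sample size
(3465 for the disorder itself, up to 757,277 for the best-powered
auxiliary trait) is the single knob controlling PGS accuracy, exactly as
in the emulated setting where the disorder's own tiny GWAS produces the
weakest score.

Real cohorts come with no generative parameters, so the remaining values
were fixed once for testability: $h^2 =
0.3$ gives all stages clear signal at desk scale, $\rho$ values span
positive, negative and strong correlations, and 2000 variants keep
kinship noise well under the pruning threshold. Consequences worth
stating plainly: the synthetic per-trait and combined $R^2_l$ are far
larger than anything reported for real cerebral-palsy PGS, and passing
tests demonstrate correctness of the machinery — scoring arithmetic,
ascertainment correction, pruning optimality, matching balance — not
realism of linkage structure (variants are LD-free), of effect-size
distributions (Gaussian, no sparsity), or of confounding (no
genotype-age dependence; population structure only through two discrete
subpopulations).

The pool is generated in memory-bounded chunks; cases are accumulated
until the target is met and controls are taken as the first sufficient
draws (exchangeable with simple random sampling since pool members are
iid). A single master seed fans out to fixed per-stage streams, so
toggling one stage never perturbs another and identical configurations
are byte-identical on disk.

# Numerical conventions and degenerate inputs

* Standardisation requires $\ge 2$ samples and nonzero variance; both are
  errors, not warnings.
* Logistic fits fail loudly on separation or non-convergence, naming the
  predictor; constant predictors are rejected up front.
* PCA mean-imputes missing dosages after centring, drops monomorphic
  variants, and errors when the requested $k$ exceeds the matrix rank;
  score orthogonality is exact to numerical precision and signs are
  arbitrary (tests compare absolute correlations).
* Bootstrap resamples containing a single class are redrawn and counted
  (`n_redrawn`).
* Kinship pairs with no usable overlapping variants are flagged
  (`n_used = 0`, `phi = NA`) rather than silently dropped.
* All report tables are written at 6 significant digits; determinism is
  end-to-end under a fixed seed.

# Problem sizes used by the test-suite

Unit and property tests run on cohorts of 40-900 samples and 100-10,000
variants; the acceptance battery uses the 322/1610 design with 200
replicates for recovery and ascertainment-invariance checks, 1000
replicates (bootstrap B = 200) for null calibration, and 10,000 variants
for kinship recovery. These sizes were chosen so each statistical
expectation has comfortable Monte-Carlo margin while the full suite stays
fast on one CPU.

# Limitations

* No LD, dominance, epistasis, X chromosome or imputation dosages; hard
  calls only.
* No strand-ambiguity resolution or genome-build liftover in
  harmonisation.
* PCs are computed on the analysis cohort itself, not projected from a
  reference panel.
* The bootstrap-Z liability test is conservative under the null (see
  above); the bootstrap lower bound is the better-calibrated summary.
* Weight *estimation* (e.g. from summary statistics with LD reference
  panels) is out of scope: weights are an input, or synthesised with
  known truth.
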