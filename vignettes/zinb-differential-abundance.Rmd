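---
title: "Zero-inflated NB differential abundance for label-free liver proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-inflated NB differential abundance for label-free liver proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zinbdap)
```

## The analysis problem

zinbdap analyzes label-free quantitative (LFQ) proteomics abundance tables
from a two-treatment feeding trial in pregnant beef cows: 24 animals split
into a control arm (CON, conventional feed-grade urea) and a post-ruminal
urea arm (PRU, rumen-protected urea), blocked by gestation group (three
insemination waves) and fetal sex. The scientific question is which hepatic
proteins change in abundance with the nitrogen-delivery route.

LFQ tables have two features that break ordinary linear-model workflows:
abundances are nonnegative, right-skewed and mean-dependent in their
variance, and they contain many exact zeros. A zero can be biological (the
protein is absent) or technical (present but below the detection limit), and
the two mechanisms need different handling. The package therefore models
each protein with a negative binomial (NB) count distribution and,
optionally, a zero-inflation (ZI) mixture component that gives zeros their
own probability mass.

## The four per-protein models

For protein abundance $y_{ijkl}$ of the $l$-th animal (treatment $i$,
gestation group $j$, fetal sex $k$), all four models share the same count
linear predictor on the natural-log scale with the log normalized library
size $LS_l$ as an offset:

$$\log \mu_{ijkl} = \log LS_l + \mu + T_i + GG_j + FS_k$$

with $y \sim \mathrm{NB}(\mu_{ijkl}, \theta)$,
$\mathrm{Var}(y) = \mu + \mu^2/\theta$ (the "size" parameterization: larger
$\theta$ means closer to Poisson). Reference levels are CON, gestation
group 1 and female, so $T$ is directly the PRU effect — a natural-log fold
change. The zero-inflated variants mix in a point mass at zero with
probability $\pi_l = \mathrm{logit}^{-1}(z_l^\top\gamma)$, so
$f(0) = \pi + (1-\pi)\,\mathrm{NB}(0)$ and $f(y>0) = (1-\pi)\,\mathrm{NB}(y)$.
The four specifications differ only in the ZI predictor:

| name | ZI terms |
|------|----------|
| `NB` | none ($\pi \equiv 0$) |
| `ZINB_basic` | intercept |
| `ZINB_TRT` | intercept + treatment |
| `ZINB_full` | intercept + treatment + gestation group + fetal sex |

Note the modelled quantity is the count $y$ with a multiplicative
library-size offset; a literal regression of $\log(y/LS)$ would not define a
valid likelihood at $y = 0$, which is precisely where the information about
zero inflation lives.

Fitting is plain maximum likelihood (BFGS with analytic gradients, a
Nelder–Mead fallback, dispersion on the log scale to keep it positive).
Starting values come from a log-linear moment fit on the positive
observations, method-of-moments dispersion, and a logit of the observed
zero excess over the NB-predicted zero fraction. A fit is reported as
non-converged — never as an error — when the optimizer fails or the observed
information for the regression coefficients is not positive definite;
non-converged models are simply not considered downstream. When the
dispersion runs to its numerically-Poisson cap (equidispersed data, e.g. a
constant response), the dispersion row is profiled out of the information
matrix so the regression coefficients still get a covariance.

### Small-sample calibration of the Wald test

Per-protein ML with $n \approx 22$ and five mean parameters underestimates
residual variance by the classic $(n-p)/n$ factor, and with it the treatment
SE; a normal-reference Wald test then rejects far too often (we measured
~9.5% at nominal 5% in a null simulation). The package therefore scales the
Wald SE by $\sqrt{n/(n-p)}$ and refers the statistic to a $t$ distribution
with $n-p$ degrees of freedom — the analogue of the $t$-tests that
mixed-model software reports. The same corrected SE enters the reported 95%
interval $\hat\beta \pm 1.96\,\mathrm{SE}$.

## Model selection and DAP calling

Models are compared per protein by a nested likelihood-ratio cascade,
simplest first: NB vs `ZINB_basic`; on rejection (entry LRT $p < 0.05$),
`ZINB_basic` vs `ZINB_TRT`; and only if `ZINB_TRT` displaced `ZINB_basic`,
`ZINB_TRT` vs `ZINB_full`. Only converged candidates are compared; a
non-converged candidate stops the cascade with a recorded status. The LRT
uses the naive $\chi^2$ reference even though the ZI-entry test sits on the
boundary of the parameter space ($\pi \to 0$), where it is conservative —
this is deliberate, because it reproduces what the standard mixed-model
software does rather than improving on it.

The treatment p-value is the Wald $t$-test on the count-part treatment
coefficient of the selected model. Across all tested proteins (those whose
NB fit converged; the run report states the denominator), p-values are
converted to Storey q-values — $\pi_0$ estimated by the smoother method on a
$\lambda$ grid, falling back to $\pi_0 = 1$ (exactly Benjamini–Hochberg) for
short vectors — and a protein is a DAP when $q < 0.05$, strict inequality. A
selected model without a finite treatment SE is reported with a status flag
and never called a DAP.

Exclusive proteins are a separate presence/absence contrast on the same
QC-filtered matrix: a protein is exclusive to a group when detected
(abundance $> 0$) in at least one sample of that group and in none of the
other. These complement the DAP test, which can only address proteins
quantified in both arms.

## Quality control and normalization

The QC chain, in enforced order: drop proteins flagged as potential
contaminants, reverse (decoy) sequences, or identified only by a
modification site; drop samples detecting fewer than 1% of the proteins
(failed acquisitions); drop proteins detected in fewer than
$\lceil 0.10 \times n_\mathrm{samples}\rceil$ samples — with 22 samples,
"2 or fewer". "Detected" means abundance strictly positive, matching the
zero-inflation framing of LFQ missingness. Library sizes are the post-filter
column sums.

Normalization factors are trimmed means of M-values (TMM) against a
reference sample: log2 abundance ratios on library-size-normalized values,
zeros excluded pairwise (no pseudocounts), double-trimmed (30% on M, 5% on
A), precision-weighted, and rescaled to geometric mean 1. The reference is
the sample whose upper quartile is closest to the mean upper quartile, the
method's customary default. The computation is delegated to edgeR's TMM
implementation behind the package's own interface, and the test suite checks
it against an independent loop-based re-derivation of the published formula.
The normalized library size entering the model offset is
`lib.size * norm.factors`.

## The synthetic-data generator

`simulate_design()` / `simulate_abundance()` generate data from exactly the
model the pipeline fits: NB counts with log-link fixed effects in
reference-level coding, per-sample library-size multipliers, and optional
logit-scale zero inflation. Design choices worth stating:

* Library sizes are drawn log-uniformly over a configurable range
  (5e4–2e5 by default); the spread of real acquisition depths is not
  reported for this kind of experiment, so the range is a plausible
  placeholder, not an inferred value.
* Each protein has its own random stream seeded by the protein index, so
  enlarging a simulation never perturbs previously generated proteins.
* Counts are drawn before zero-inflation indicators, so a ZI configuration
  with $\pi = 0$ reproduces the non-ZI data stream exactly — useful for
  differential testing of the ZI machinery.
* Default dispersion $\theta = 10$ (counts CV ~32% at large $\mu$) for
  generic simulations; the study-emulation default is $\theta = 1000$ (CV
  ~3%), back-calculated from the magnitudes of the published Wald
  statistics (q-values of $10^{-9}$ to $10^{-271}$ at ln fold changes of
  0.07–1.5 with 22 animals imply a residual CV near 3%).

`simulate_study()` emulates the full published dataset so each pipeline
stage has a known truth: 807 identified protein groups, 30 flagged; two CON
samples that failed acquisition (<1% detection, removed by sample QC,
leaving 10 CON + 12 PRU); 395 proteins detected in ≤2 samples (removed by
the sparsity filter); and a retained panel of 382 proteins containing 19
proteins carrying the reported ln fold changes (0.49, 0.58, 1.03, 0.26,
0.24, 0.17, 0.16, −1.53, −1.48, −1.15, −0.35, −0.36, −0.18, −0.24, −0.11,
−0.11, −0.08, −0.07, −0.08).

The remaining 363 retained proteins come in two compositions. The
`"exclusive"` composition mirrors the published dataset: 280 proteins
detected only in PRU and 83 only in CON (each in ≥3 samples of its group,
so they survive the sparsity filter; 280 + 83 + 19 = 382). This composition
has a consequence worth understanding: the only proteins co-detected across
arms are then the 19 effect-carrying ones, so TMM has no null proteins to
anchor on and absorbs the trimmed mean of those effects (≈0.06 on the ln
scale) into the normalization factors. Fold changes are then identifiable
only up to that location shift, and the weakest effects (|lnFC| ≤ 0.08)
become undetectable — an inherent property of ratio-based normalization on
presence/absence-dominated data, not an implementation artifact. The
`"anchored"` composition therefore replaces the exclusive proteins with 363
shared null proteins, keeping the design, dispersion, panel size and
planted effects identical; it is the configuration used for effect-recovery
benchmarks, while the `"exclusive"` composition exercises the QC and
exclusive-detection stages.

What the generator does *not* emulate: correlated missingness across
proteins, intensity-dependent detection probability, peptide-level roll-up
noise, and between-protein abundance correlation. Passing tests demonstrate
that the algorithms are correct under the stated generative model, not that
the model captures every feature of real LFQ data.

## Animal-trait analysis

Performance, blood and urine traits follow a fixed-effects Gaussian model:
treatment, gestation group, fetal sex, and the initial body weight of the
cow as a covariate, $e \sim N(0, I\sigma_e^2)$. Two workflow rules are
implemented as stated procedures:

* The initial-BW covariate is retained only when highly significant
  ($p < 10^{-5}$); otherwise the model is refit without it.
* Outliers are removed iteratively: fit, compute externally studentized
  (leave-one-out) residuals, remove the single worst observation beyond
  ±3, refit; stop when none remain, abort if more than 20% of the data
  would go. Ties break by input order. Residual normality is summarized by
  a Shapiro–Wilk p-value and reported — never used to auto-reject.
  "Studentized" is read as the deletion form, its conventional meaning in a
  removal rule; internally studentized residuals are available via a flag.

Least-squares means use balanced factor weights (emmeans). For the two-level
treatment factor in this additive model the LS-mean contrast t-test
coincides with the coefficient t-test, which is what `fit_trait()` reports.
The treatment test of the plain Eq-1 fit is calibrated (type-I error at
nominal level in the suite's 1000-replicate null calibration). The outlier
screen, applied to data that satisfy the model, makes the test
anti-conservative (removing extreme residuals shrinks the variance
estimate); the calibration check therefore addresses the model's test
itself, and the screen should be viewed as a data-cleaning step for real
data containing gross errors, not as a power enhancement. Significance is
declared at $p < 0.05$ and trends at $0.05 < p \le 0.10$.

## Nutrition arithmetic

Deterministic identities on a dry-matter basis: non-fibrous carbohydrates by
difference, $\mathrm{NFC} = 1000 - (\mathrm{CP} + \mathrm{EE} +
\mathrm{NDFap} + \mathrm{ash})$ g/kg DM; fecal DM excretion from the
indigestible NDF internal marker (240-h ruminal incubation), fecal DM =
marker intake / fecal marker concentration, with marker recovery assumed
100% and exposed as a parameter; apparent digestibility
$1 - \mathrm{fecal}/\mathrm{intake}$ per component (fecal output above
intake is clipped with a warning); and total digestible nutrients with the
conventional 2.25 fat multiplier,
$\mathrm{TDN} = \mathrm{dCP} + \mathrm{dNFC} + \mathrm{dNDFap} +
2.25\,\mathrm{dEE}$.

## Worked example

```{r example}
st <- simulate_study(seed = 1, composition = "anchored")
res <- run_dap_pipeline(st)
res$report$n_dap
head(res$results[res$results$is_dap,
                 c("protein_id", "selected_model", "treatment_q", "ln_fc")])
```

## Numerical choices and problem sizes

Tolerances: optimizer relative tolerance 1e-12 with a 500-iteration cap;
LRT statistics floored at 0; q-value monotonicity enforced by the step-up
construction; the dispersion cap $e^{25}$ marks the numerically-Poisson
regime. The test suite's simulation sizes — 500 proteins for recovery and
null-calibration runs at 22–96 animals, 12 seeds for the global-null FDR
check, 1000 replicates for the Eq-1 calibration — were chosen to keep
Monte-Carlo error well below the tolerances being asserted while remaining
comfortable on a single CPU.

## Known limitations

* No empirical-Bayes dispersion shrinkage or moderated statistics:
  per-protein ML is the modelled procedure, and with ~22 samples its
  small-sample behavior is handled by the df correction, not by information
  sharing across proteins.
* LFQ intensities are rounded to integers at simulation/ingestion so the NB
  likelihood is a true pmf; a continuous quasi-likelihood reading is noted
  but not implemented.
* The ZI-entry LRT is conservative at the boundary (no 50:50 mixture
  correction), matching standard software behavior.
* Exclusive-protein sets and fold-change identifiability interact with
  normalization when co-detection is sparse, as described above.
* No batch correction, no imputation, no random effects.
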