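---
title: "Methods: cost-effectiveness of a pharmacy-only ART refill program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-effectiveness of a pharmacy-only ART refill program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refillcea)
```

`refillcea` evaluates a pharmacy-only refill program (PRP) for
antiretroviral therapy against standard physician-led care (SOC) in a
two-strategy decision model, and provides a synthetic retrospective cohort
so the effectiveness stage can be exercised without the original clinic
database. This vignette documents the model, its parameters and defaults,
the design decisions that were genuinely open, and what the synthetic data
can and cannot show.

## The decision model

Each strategy carries an annual per-patient cost, split into nine
categories, and a probability of a favourable immune response (FIR,
follow-up CD4 count > 500 cells/µL). Two perspectives are supported:
*limited societal* (all categories; no productivity losses) and *Ministry
of Health* (direct medical only — patient transport and lost patient time
are excluded). The bundled parameter set (2009 US$) uses the published
component costs — ART $243, other drugs $35, radiology $2, laboratory $34,
personnel $10 (PRP) / $31 (SOC), overhead and capital $141, transport $20,
lost patient time $4 (PRP) / $16 (SOC) — and the published totals (PRP
520/496, SOC 655/610 under societal/MoH), with FIR probabilities 0.186
(PRP) and 0.196 (SOC) and arm sizes 578/251.

### Cost reconciliation and the residual category

The published components do not sum to the published totals: PRP components
give 489 against a societal total of 520, SOC components 522 against 655.
We keep the totals authoritative for the headline analysis and carry the
gap as a `residual` category ($31 PRP, $133 SOC), so component-level
sensitivity analysis and the published totals coexist. With the residual,
PRP reconciles exactly under both perspectives and SOC under the societal
perspective; the SOC MoH total (610) still differs from its component sum
(619) by $9. `perspective_total()` returns the published 610 and emits a
reconciliation warning, which is therefore expected when evaluating the
bundled model under the MoH perspective. Whether the residual reflects
arm-specific drug or laboratory utilisation is unknown; it is an accounting
device, not a claim.

Costs are annual while effects accrue over the ~13-month follow-up; no
time alignment or discounting is applied, matching the source analysis.

## Deterministic analysis

`incremental()` gives ΔC and ΔE (intervention minus comparator); `icer()`
reports |ΔC/ΔE| with the cost-effectiveness-plane quadrant. A signed ratio
is ambiguous in the NW/SW quadrants, so the quadrant plus interpretation
text carries the sign information; in the SW quadrant the ICER reads as
savings per FIR forgone. The ICER is undefined exactly when ΔE = 0
(quadrant `axis`). `nmb()` computes net monetary benefit λ·p − C;
ties are broken toward the comparator, a conservative default that affects
only a measure-zero set of λ. With the bundled parameters:

```{r}
model <- prp_decision_model()
cea(model)
```

## Uncertainty analysis

One-way ranges follow fixed rules: costs halved and doubled, probabilities
varied by ±20% (capped at 1). Treating each range as a 95% confidence
interval gives `se = (high − low)/(2 × 1.959964)`. Probabilities are then
moment-matched to beta distributions and costs to gamma distributions;
both fits reproduce the target mean exactly (algebraically) and the test
suite verifies mean and SD against 10^6 sampled draws at 0.5% relative
tolerance. Zero-valued costs have degenerate ranges and are excluded with
a warning.

### Correlation structure across arms

The sampling correlation of cost draws between arms is a genuinely open
choice. We distinguish:

- **shared categories** — equal in both arms (ART, other drugs, radiology,
  laboratory, overhead/capital, transport): one draw per iteration applied
  to both arms, so they cancel exactly in ΔC;
- **arm-specific categories** — personnel and lost patient time: drawn
  independently per arm;
- **the residual** — a fixed per-arm offset in the probabilistic analysis,
  not sampled.

Under this default every Monte Carlo iteration is cost-saving: ΔC is the
fixed residual gap (−$102) plus small arm-specific differences whose
spread (SD ≈ $14) cannot bridge it. This is the only structure consistent
with the observation that all replicates lie below zero on the cost axis.
Sampling the SOC residual (mean 133, SE ≈ 51) would place a small fraction
of draws above zero; set `include_residual = TRUE` in
`build_uncertain_params()` to explore that variant. The two FIR
probabilities are drawn independently. With `shared = FALSE` every
category is drawn per arm — the mode in which the one-way tornado is most
sensitive to the ART cost, since a shared ART draw contributes zero swing
to ΔC. The tornado therefore defaults to including the residual as a
varied parameter, while the PSA holds it fixed; both choices are
configurable and neither is asserted to be the source analysis's exact
procedure, which is not documented.

One caveat: at the MoH perspective the component-level PSA mean of ΔC is
−$123, not the published −$114, because of the $9 SOC reconciliation gap
noted above. The deterministic analysis uses the published totals; the PSA
is component-based and defaults to the societal perspective.

### Monte Carlo mechanics

`run_psa()` draws each parameter once per iteration in the fixed row order
of the parameter table (probabilities first, then shared costs in category
order, then arm-specific costs), from a single seeded generator, so runs
are bit-reproducible at a fixed seed and package version. The CEAC
evaluates `P(λ·ΔE − ΔC > 0)` on a willingness-to-pay grid of 0–30,000
US$/FIR in steps of 100 (ties at exactly zero incremental net benefit
count toward the comparator, consistent with the NMB tie-break), and the
curve crossover is located by linear interpolation between the bracketing
grid points. At 10,000 iterations the crossover's Monte Carlo standard
error is roughly $450 (delta method: the slope of the acceptability curve
near 0.5 is ≈ φ(0)·|ΔE|/sd(ΔNMB) ≈ 1.1×10⁻⁵ per dollar, and the binomial
SE of each curve point is ≈ 0.005), so repeated runs scatter within a few
hundred dollars of the deterministic root at $13,500.

```{r}
draws <- run_psa(model, n_iter = 10000, seed = 2009)
plane_summary(draws)
ceac_crossover(ceac(draws))
```

## The synthetic cohort

`generate_cohort()` emulates the published cohort's covariate structure:
per-arm truncated normals for age, ART duration, follow-up time and the
two CD4 counts, and per-arm frequencies for gender, initial and current
regimen, opportunistic-infection flags and adherence. Where the published
table and running text disagree on which arm a continuous value belongs to
(the table's column labels appear transposed for those rows), we follow the
text: the PRP arm is older (38.8 y), longer on ART (41.8 mo), has lower
baseline CD4 (218 cells/µL) and shorter follow-up (12.8 mo). Variables the
text does not assign use the table columns as labelled, and one row whose
printed percentages are crossed against its counts (opportunistic
infections at follow-up) is derived from the counts.

Arm assignment carries the program's selection bias: PRP members are
rejection-sampled to satisfy the database-observable eligibility criteria
(baseline CD4 > 200 cells/µL, ≥ 12 months on ART, optimal self-reported
adherence). The remaining criteria (visit adherence, disclosure,
pregnancy, recent clinical events) never enter the published regression
and are collapsed into a single latent pass probability in
`apply_prp_eligibility()` (default 1). Under the default constraint the
PRP arm is 100% adherence-optimal rather than the observed 98.4% — the
small observed sub-optimal fraction presumably reflects post-enrolment
drift, which the generator does not model; set `constrain_prp = FALSE` to
reproduce the raw marginal frequencies instead.

The outcome is a latent FIR Bernoulli from a logistic model whose default
coefficients are the published adjusted log odds ratios (arm effect
log 0.93); the intercept (−1.5363) was calibrated by
`calibrate_fir_intercept()` so the pooled marginal prevalence is 18.9%.
The follow-up CD4 count is then drawn from a lognormal (meanlog log 350,
sdlog 0.55) truncated above or below 500 cells/µL according to the latent
draw, and `fir` is recomputed from the stored count. The published
follow-up CD4 band proportions are internally inconsistent (five
percentages for four bands), so band-level calibration beyond the 500
cut-point is deliberately not attempted; within-band CD4 shapes are
plausible but uncalibrated. Covariates are drawn independently within arm
(no within-patient correlation between, say, baseline CD4 and CD4 at ART
start), there is no loss to follow-up, and no longitudinal structure.
Passing tests on this generator therefore demonstrate that the estimators
recover known truth under the configured structure — not that the real
cohort satisfies that structure.

## Effectiveness estimation

`fir_proportions()`, `odds_ratio_2x2()`/`crude_or()` (Wald CI; with a zero
cell the Haldane–Anscombe +0.5 correction is applied with a warning, or an
error if disabled) and `fit_fir_logistic()` mirror the published analysis:
follow-up dichotomised at one year, ART duration in three bands (<2, 2–3,
>3 years), CD4 at ART start in three bands (<200, 200–300, >300), and the
published regimen reference levels. Records with missing adherence are
dropped. Fitting is maximum likelihood by iteratively reweighted least
squares (relative deviance tolerance 10⁻⁸, at most 100 iterations) with
Wald standard errors from the inverse observed information; any
coefficient beyond ±15 on the log-odds scale is treated as evidence of
separation and flags the fit non-converged rather than returning silently.
When the arm indicator is the only covariate the exponentiated coefficient
equals the crude 2×2 odds ratio, which the tests assert to 10⁻⁶.

## Problem sizes and test design

The test suite checks covariate moments at n = 10,000 per arm against
truncated-normal oracles (3 standard errors), distribution fits against
10⁶ draws, FIR marginals at n = 20,000 per arm against numerically
integrated model probabilities, and parameter recovery of the arm log odds
ratio over 500 replicate cohorts at the published arm sizes (578/251),
requiring ≥ 93% Wald-CI coverage; separated replicates count as
non-covered. These sizes keep each property sharp enough to detect real
errors while the full suite runs in a couple of minutes.

## Known limitations

- The outcome is an intermediate immunological marker over ~13 months; no
  life-years, QALYs, discounting or multi-period structure.
- Exactly two strategies; no value-of-information analysis; no copula
  correlation between parameters beyond the shared/arm-specific split.
- The residual cost category and the $9 MoH gap are inherited
  inconsistencies of the published inputs, handled transparently rather
  than resolved.
- The synthetic cohort is a stand-in: its covariates are independent
  within arm and its selection mechanism uses only the observable
  criteria.
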