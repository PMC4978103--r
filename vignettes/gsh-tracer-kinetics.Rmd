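---
title: "Estimating glutathione synthesis rates from 13C-cysteine tracer kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating glutathione synthesis rates from 13C-cysteine tracer kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gshkin)
```

## The measurement problem

Glutathione (GSH, the tripeptide gamma-glutamyl-cysteinyl-glycine) is the
main intracellular thiol antioxidant, and its tissue concentration falls
under severe stress such as burn injury. A concentration alone cannot say
whether the pool shrank because synthesis slowed or because consumption
accelerated. Stable-isotope tracer kinetics separates the two: infuse
[1-13C]cysteine — the limiting GSH precursor — at a constant rate, and watch
the label appear in GSH.

`gshkin` implements the three estimators this design supports, plus the
surrounding processing, statistics, and a synthetic-cohort simulator of the
sham-burn/burn rabbit experiment (7 sham, 6 burned animals; 6-h primed
constant infusion; blood sampled at 0, 60, 120, 180, 240, 270, 300 and
360 min; organs taken at the end).

## Models and estimators

### Plasma cysteine flux (steady-state isotope dilution)

Under a primed constant infusion at rate $i$ (umol/kg/min) and tracer
abundance $E_i$, the plasma precursor enrichment settles at a plateau
$E_p$. Mass balance at isotopic steady state gives the rate of appearance

$$Q = 60\, i\, (E_i/E_p - 1) \qquad [\mu\mathrm{mol/kg/h}].$$

`check_plateau()` verifies flatness by ordinary least-squares regression of
enrichment on time over 120–360 min: the plateau is accepted when the
two-sided slope t-test does not reject at $\alpha = 0.05$. $E_p$ is the
arithmetic window mean, not the regression intercept — the regression is
only a flatness diagnostic. A failed check is logged and flux is still
computed, flagged, so every animal appears in the output.

### Whole-blood GSH synthesis (precursor–product)

With the precursor held at $E_p$, product enrichment rises linearly; the
slope $K$ (mole-fraction excess/min, `fit_product_slope()`, OLS with free
intercept) yields the fractional synthesis rate

$$FSR = 1440\,K/E_p \qquad [\mathrm{day}^{-1}],$$

and the absolute rate $ASR = FSR \times C_{gsh}$ (umol/l/day). The free
intercept tolerates a short tracer-equilibration lag and is exact under the
linear model either way. FSRs are computed per animal and then averaged
(mean of ratios); the group mean of per-animal ASRs is generally not the
product of the group means, and the pipeline reports the former.

### Organ GSH synthesis (single end-point, single exponential)

Organs are sampled once, at the end of the infusion, so a slope is not
available. Label incorporation into a constant pool with precursor
enrichment $E_o$ (the tissue free-cysteine enrichment measured in the same
homogenate — not the plasma plateau) follows

$$E_t = E_o\,(1 - e^{-k t}), \qquad
  k = -\ln(1 - E_t/E_o)\,\frac{1440}{t} \quad [\mathrm{day}^{-1}],$$

with $t = 360$ min by default (configurable per sample). `organ_fsr()`
treats $E_t \ge E_o$ — possible under read noise — as a model violation and
refuses to produce a rate: clamping just below $E_o$ would fabricate an
arbitrarily large finite $k$. Such samples are flagged and excluded, the
same handling given to failed determinations.

## Enrichment processing

Enrichments are mole-fraction excess: the tracer-channel fraction
$R = I_{M+1}/(I_{M0} + I_{M+1})$ of the monitored ion cluster (m/z
477.1–480.1 for the GSH derivative), minus the pre-infusion baseline
fraction (`compute_mre()`). The internal standard for concentration —
doubly labeled on the glycyl residue — sits at M+2 and stays out of the
enrichment ratio; full natural-abundance isotopomer deconvolution is out of
scope, as baseline subtraction removes the leading term. Concentrations
come from the internal-standard ratio (`quantify_gsh_concentration()`).
The method's quantitation limit is 0.3–0.5 mol% excess; `apply_loq_filter()`
defaults to the conservative lower bound 0.003. Flagged values are kept,
not zeroed or dropped from the data, so that exclusion decisions stay
visible and reversible; negative post-subtraction values are retained
unclipped to keep regressions unbiased.

## The synthetic cohort

`simulate_cohort()` generates the full experiment so every stage is
testable without data:

* **Group truth.** Defaults (`default_truth_from_tables()`) are the
  published group means: flux 29.3 vs 65.6 umol/kg/h, blood FSR 0.46 vs
  0.38/day, blood GSH 1486.0 vs 1263.8 umol/l, and the per-organ FSRs and
  concentrations (liver 5.86 vs 3.76/day at 2.00 vs 0.61 umol/g, etc.).
  Burned muscle carries `NA` truth: its determination failed in the
  experiment, and the simulator reproduces that as a sample with no
  reliable enrichment or concentration, which the pipeline must flag and
  exclude.
* **Plasma forward model.** One-pool kinetics. The 60-min priming bolus is
  assumed ideal by default (`prime_fraction = 1`): the prime exactly fills
  the tracer pool, the enrichment is flat at $E_p$ from the first
  post-baseline sample, and noiseless data invert *exactly* to the truth —
  the round-trip identity the estimation tests rely on. Setting
  `prime_fraction < 1` produces the familiar rising approach
  $E_p(1-(1-m)e^{-\lambda t})$ with $\lambda = \ln(100)/60$ per min (99% of
  plateau reached 60 min into an unprimed infusion), for studying plateau
  diagnostics under imperfect priming.
* **Between-animal variability.** Mean-one lognormal factors on rates
  (`animal_cv = 0.25`) and concentrations (`concentration_cv = 0.20`), so
  simulated rates stay positive and group SEMs come out on the order of the
  published ones (published CVs range roughly 0.13–0.6 across variables; a
  single CV per quantity class is deliberately simple).
* **Read noise.** Gaussian, `ms_read_sd = 0.005` mole-fraction excess per
  enrichment read. Within-replicate instrument variance is not published;
  this is a stated assumption chosen to be of the order of the quantitation
  limit.
* **Tissue precursor dilution.** Organ free-cysteine enrichment is the
  plasma plateau scaled by a tissue factor (liver 0.60, lung 0.55, kidney
  0.70, muscle 0.45) — tissue precursor pools sit below plasma, and the
  factors are fixed descriptive constants in the observed 0.4–0.9 range,
  not fitted quantities.

What the simulator does **not** emulate: correlated multi-organ physiology,
time-varying fluxes, inter-organ GSH transport, plasma/erythrocyte
compartmentation, or heavier-tailed instrument error. Passing tests
demonstrate estimator correctness and statistical behaviour under the
stated generative model, not robustness to every feature of real data.

## Group statistics

Results are summarised as mean ± SEM. Each variable is screened per group
with the Shapiro–Wilk test at $\alpha_{norm} = 0.05$; if both groups are
consistent with normality the groups are compared with a pooled-variance
two-sided t-test (the classic independent-samples variant; Welch available
via `var_equal = FALSE`), otherwise with a two-sided Wilcoxon rank-sum test
(exact p for these group sizes when untied). No multiple-testing
correction is applied, matching common practice for a single planned
contrast per variable. Groups smaller than 3 cannot be screened and fall
back to the rank test with a warning.

## Numerical and design notes

* **Units.** Minutes internally; day/hour conversions are the exact
  factors 1440 and 60, applied once at the reporting boundary.
* **Enrichment convention.** All enrichments are mole-fraction
  (tracer/(tracer+tracee)) excess. The printed fluxes are reproduced under
  this convention with $E_i = 0.99$; ratio-form enrichments would not
  reproduce them.
* **ASR units.** ASR is FSR × concentration per *day* (umol/l/day blood,
  umol/g/day organs); the per-day definition is the one consistent with the
  published FSR and concentration means.
* **Degenerate inputs.** Exactly constant series give slope 0 and are
  accepted as plateaus; slopes below 1e-15 are snapped to 0 rather than
  reported as spurious negatives; `Ep >= Ei`, `Et >= Eo`, zero
  internal-standard signal and non-positive pool sizes raise errors rather
  than propagate nonsense.
* **LOQ censoring bias.** Excluding sub-LOQ product points interacts with
  regression: when the true 60-min product enrichment is near the LOQ
  (burned blood GSH, ~0.007), low-reading points are censored
  preferentially, flattening the fitted slope slightly (about −2% on the
  burned blood FSR at default noise). This is a property of LOQ censoring
  itself, kept visible rather than corrected.
* **Cohort sizes.** Methods-style default of 7 sham / 6 burned (the figure
  caption swaps them); both are configurable.
* **Problem sizes in the test-suite simulations** — 200 cohorts for bias
  and direction checks, 1000 replicates for the plateau type-I error,
  2000 for the comparison-test level — were chosen as the smallest sizes at
  which the Monte-Carlo standard error is well below each property's
  acceptance margin.

## Known limitations

* The single-exponential organ model assumes a constant pool and constant
  precursor enrichment over the infusion; a rising tissue precursor biases
  single-point $k$ downward.
* The kidney contrast illustrates a power limit: with the default
  between-animal CV of 0.25 and the small true difference between group
  means (3.58 vs 4.06/day), the "no difference" outcome reproduces in only
  ~88% of simulated cohorts — a property of the generative conditions, not
  of the estimator.
* Flux is reported as total rate of appearance; the tracer's own
  contribution is not subtracted.
* No compartmental multi-pool modeling, non-steady-state (Steele)
  corrections, or inter-organ transport terms.
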