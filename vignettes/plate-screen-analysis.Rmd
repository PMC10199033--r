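---
title: "Analyzing automated 96-well multi-omics screens with plateomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing automated 96-well multi-omics screens with plateomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateomics)
library(dplyr)
```

plateomics is the data-analysis layer for robotic microplate screening of
microbial cultures: 96-well batch cultivations read repeatedly by an on-deck
spectrophotometer, sampled once near the end of the run for exo-metabolome,
endo-metabolome, proteome and proteinogenic amino-acid labeling
measurements. This vignette explains the models behind each stage, the
parameters that matter, the choices made where several designs were
defensible, and what the synthetic-data tests do and do not establish.

## Growth curves

### The measurement model

Each well is sampled (5 µL, diluted 5-fold to 25 µL) before every OD read,
so the recorded absorbance is the culture OD divided by the dilution
factor; `assemble_well_series()` multiplies it back. Two further optical
effects sit on top of the biological signal:

* **Evaporation.** Sealed-lid plates still lose volume slowly, which
  concentrates everything in the well. An inert dye (OrangeG) in dedicated
  control wells reports this directly: its OD450 rises as volume falls.
  `fit_volume_loss()` normalizes the mean dye trace to its first reading
  and fits a line; the correction factor at time $t$ is
  $c(t) = 1 + \beta\,(t - t_0)$, which is exactly 1 at the first timepoint
  — the one reading taken before any loss has accumulated. Experimental
  OD600 values are divided by $c(t)$. A negative $\beta$ (dye apparently
  diluting) is physically implausible and raises a warning rather than an
  error, since condensation return can transiently produce it.
* **Background.** Media color and plate optics add an offset; the mean
  OD600 of the dye control wells estimates it per timepoint and is
  subtracted.

Background is subtracted *before* dividing by the volume factor. The
package treats the background as part of the (evaporation-concentrated)
optical signal, so this order makes a noiseless simulated well recover its
true curve exactly; the reverse order leaves a residual of order
`background * evap_rate * t` (≈ 0.004 OD units over a 10 h run), small but
avoidable. Corrected values that land below zero are masked as missing
rather than clamped, so that log-space fits are not biased by a floor.

### Growth rates

`specific_growth_rates()` estimates $\mu(t) = d\log \mathrm{OD}/dt$ as the
slope of $\log$ OD600 over a centered rolling window (default 5 points,
i.e. 2 h at the platform's 30-min reading interval). Values at or below
`min_od = 0.01` are masked first: at the instrument's noise floor the log
transform amplifies noise without bound. Edge points use truncated
windows.

`find_exponential_phase()` scans every contiguous window of at least 5
usable points and keeps those whose log-linear fit has $r^2 \ge 0.95$ and a
positive slope; among windows whose slope is within 10% of the best
qualifying slope it returns the longest, breaking ties toward the earlier
start. The thresholds trade window length against purity: a longest-window
rule alone drifts into lag and stationary phase, a max-slope rule alone
returns the shortest window that noise happens to favour. With these
defaults the detected window on a lag/exponential/plateau test curve
brackets the true exponential segment to within one reading interval on
each side. On curves with no qualifying window the well is flagged
`no_growth` rather than given a rate.

`fit_mu_max()` offers two estimators, mirroring the two ways plate screens
are commonly summarised:

* `log_linear` — the slope of $\log$ OD600 over the detected window, with
  its standard error. Simple and robust, but on saturating curves the
  window-based slope sits a few percent below the true maximal rate
  because no finite window is free of curvature.
* `parametric` (default) — a logistic curve
  $\mathrm{OD}(t) = K N_0 e^{\mu t}/(K + N_0(e^{\mu t} - 1))$
  fitted to the untransformed series by Levenberg–Marquardt least squares;
  $\mu$ is the model's per-capita rate in the low-density limit, i.e. the
  maximum specific growth rate. On noiseless logistic input it is exact,
  which is why the volume-correction efficacy checks use it. A fit that
  fails to converge falls back to `log_linear` and flags `poor_fit`.

`plate_growth_summary()` reports the mean and SD of $\mu_{max}$ over sample
wells and flags the plate as contaminated if any media-only control well
gains more than 0.05 corrected OD600 units over the run — comfortably above
reading noise, well below any real culture's signal.

```{r growth-demo}
sim <- simulate_plate(seed = 1, mu_true = c("E. coli" = 0.594))
res <- analyze_growth(sim$readings, sim$layout)
res$summary |> select(n_sample_wells, mu_mean, mu_sd, contaminated)
```

## Uptake and secretion rates

During balanced exponential growth, the change of an extracellular
compound's concentration relative to fresh medium is proportional to the
biomass formed; the proportionality constant is the yield $Y$ in
mmol gDCW$^{-1}$, and the specific exchange rate is $q = Y \mu$
(mmol gDCW$^{-1}$ h$^{-1}$). Sampling parallel cultures started at
different dilutions once, at the end of the run, therefore traces out the
same line as sampling one culture over time — the single-time-point
strategy. `estimate_exchange_rate()` fits the line by ordinary least
squares and gates the estimate on $n \ge 3$ points and $r^2 > 0.8$.

Two choices here were genuinely open:

* **Initial-concentration subtraction.** Measured concentrations are
  referenced against a fresh-medium composition table (`medium`
  argument). For substrates this is mandatory — glucose starts at
  4 g/L ≈ 22.2 mM, not zero — and for products it subtracts nothing, so it
  is applied uniformly.
* **Intercept.** The regression uses a free intercept by default: medium
  carry-over and background offsets shift all points equally, and a free
  intercept absorbs them at the cost of one degree of freedom. A
  through-origin fit is available via `intercept = FALSE`.

Biomass at sampling comes from OD600 via organism-specific conversion
factors (2.06 gDW L$^{-1}$ OD$^{-1}$ for *E. coli*, 3.62 for *P. putida*,
3.31 for *S. cerevisiae*); `biomass_sampled()` multiplies volume, OD and
factor. Consumption is negative internally, and every estimate carries an
explicit `direction` label so downstream code never has to guess the sign
convention.

## Quantification and energy charge

Absolute quantification of AMP/ADP/ATP uses isotope dilution: every sample
and standard is spiked with a fully ¹³C-labeled internal standard, and the
12C/13C peak-area ratio — not the raw area — is calibrated against
standards (`fit_calibration()`) and inverted (`quantify()`). The
calibration model is linear; a `1/x` weighting option stabilises the
relative error at the low end when the residual spread grows with
concentration, and the unweighted fit remains the default since the
package cannot know the instrument's noise structure. Quantities outside
the calibrated range are flagged `extrapolated` rather than clipped.

Concentrations are normalized to biomass by
$c\;[\mu\mathrm{mol\,gDCW^{-1}}] = c\;[\mu M] \times 10^{-3} \times
V_{recon}\;[\mathrm{mL}] / X\;[\mathrm{gDCW}]$
(`normalize_concentration()`), and quenching quality is summarised by the
adenylate energy charge
$\mathrm{EC} = (\mathrm{ATP} + \tfrac12\,\mathrm{ADP}) /
(\mathrm{ATP} + \mathrm{ADP} + \mathrm{AMP})$,
which is close to 1 in healthy exponentially growing cells and drops when
metabolites degrade during sampling. EC is scale-invariant, so it is
meaningful even when only relative pool sizes are trusted.

```{r ec-demo}
energy_charge(atp = 2.8, adp = 0.9, amp = 0.2)
```

## Plate QC

`plate_cv()` computes the per-feature replicate CV (sample SD over mean,
percent) and the share of features below a threshold; features with
non-positive means have undefined CV and leave the denominator, because a
ratio to a zero or negative mean is meaningless, and silently including it
as 0 or Inf would distort the summary either way. `flag_outlier_wells()`
scores each well by the median over features of its robust z-score
(per-feature median/MAD) and flags wells above 3 — a deliberately blunt
whole-well rule aimed at clogged filters and failed injections, not at
single-feature anomalies. `proteome_coverage()` is the detected/coding
percentage.

## Natural-abundance correction of MDVs

A measured mass-distribution vector (MDV) of a derivatized amino-acid
fragment mixes the tracer labeling of its backbone carbons with the
natural heavy-isotope background of everything else — H, N, O, the two or
three silicons of the TBDMS groups, and the non-backbone carbons.
`natural_distribution()` builds theoretical isotopologue distributions by
convolving per-element multinomial distributions (full multinomial for O,
S and Si, whose M+2 isotopes matter; no binomial shortcut), truncated at
`k_max` with the truncated mass reported. `build_correction_matrix()`
assembles, for each backbone labeling state $j$, the distribution the
instrument would measure — the natural distribution of the residual
formula convolved with the remaining unlabeled backbone carbons, shifted
by $j$ — and `correct_mdv()` solves the resulting system by nonnegative
least squares, renormalizing the solution. NNLS rather than plain matrix
inversion keeps abundances nonnegative in the presence of noise; in the
noiseless case the two coincide and the round trip is exact to numerical
precision. The default mass window `k_max = n_backbone + 4` captures
more than 99% of every column's probability for the shipped TBDMS
fragment set.

The shipped fragment library covers the [M-57] fragments of 14
proteinogenic amino acids with their full derivatized elemental
compositions, and the isotope-abundance table uses standard terrestrial
values; both are plain text files under `extdata/` and can be replaced.

```{r mdv-demo}
m <- build_correction_matrix("C11H26NO2Si2", n_backbone = 3)
round(m[1:4, ], 4)
```

## The synthetic plate simulator

Every pipeline stage is tested against `simulate_*()` generators that emit
machine-readable ground truth. The defaults encode the study conditions
the pipeline is meant for:

* 80 sample wells plus 8 controls (4 OrangeG volume controls, 2 media-only
  contamination controls, 2 growth controls), readings every 0.5 h for
  10 h;
* logistic growth from OD 0.05 towards 1.5 at organism rates taken from
  plate-scale measurements (e.g. 0.594 h⁻¹ for aerobic *E. coli*,
  0.403 for *S. cerevisiae*, 0.845 for *P. putida*), with 3% between-well
  rate jitter — the spread consistent with observed plate SDs of
  0.02–0.03 h⁻¹;
* linear relative volume loss at 1%/h, matching the linear dye model the
  analysis fits (an exponential loss model would make the dye trace
  curved, which the data do not show at these rates);
* 2% multiplicative lognormal reading noise, a constant 0.04 OD media
  background, and 5-fold measurement dilution;
* exo-metabolome series with glucose at 22.2 mM in fresh medium and
  signed yields per compound; MDV noise additive truncated-normal with
  SD 0.003, the magnitude at which a simulated unlabeled plate deviates
  from theory by about 1 mol% at worst;
* optional edge-effect gradient on growth and evaporation rates, off by
  default (the platform's sealed lid makes edge wells behave like center
  wells).

What the simulator does **not** emulate: diauxie and other non-logistic
growth shapes, oxygen limitation, instrument drift within a read, carryover
between wells, chromatographic peak-integration errors, and deviations
from isotopic steady state. Passing recovery tests therefore shows the
estimators are correct for the stated measurement model, not that real
cultures obey that model; the QC statistics (r² gates, CV fractions,
contamination and outlier flags) are the run-time guards for the latter.

## Numerical choices and limitations

* Problem sizes in the tests and the acceptance script: 80-well plates
  with 21 timepoints per organism, 100-seed replicate loops for exchange
  rates and MDV round trips, 50-seed loops for outlier false positives —
  the full suite runs in well under a minute on a laptop core.
* Random-number use is always behind an explicit `seed` argument
  (`withr::local_seed`), so identical calls are bit-identical.
* Degenerate inputs fail loudly: zero internal-standard area, zero biomass,
  all-zero adenylate pools, singular dilution regressions, mismatched MDV
  dimensions and misaligned timepoints are errors, never silent repairs.
* The log-linear and parametric growth estimators disagree by a few
  percent on saturating curves (window curvature); both are reported
  rather than hiding the choice. The parametric fit assumes a logistic
  shape and will flag rather than fit curves far from it.
* The single-time-point exchange-rate strategy assumes balanced growth at
  sampling and a common yield across dilutions; it is a screening-grade
  estimator, and the r² gate plus the replicate CV are its guardrails.
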