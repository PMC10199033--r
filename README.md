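# plateomics

Analysis toolkit for automated 96-well multi-omics screens of microbial
cultures — the kind of experiment where a liquid-handling robot grows a
plate of *E. coli*, *S. cerevisiae* or *P. putida* batch cultures, reads
OD450/OD600 every 30 minutes, and samples wells for exo-metabolome (HPLC),
endo-metabolome (LC-MS), proteome and proteinogenic amino-acid labeling
(GC-MS) measurements. plateomics turns the resulting tables into
physiological quantities with quality control at every step. It is aimed
at labs running plate-based phenotyping or screening who need
reproducible, scriptable processing rather than per-experiment
spreadsheets.

Everything is data-frame in, tibble out, so the functions compose with the
pipe; fitted objects have `tidy()`/`glance()` methods and `autoplot()`/
`plot_*()` figures.

## What it computes

**Growth.** Per-well OD600 series are corrected for evaporation using the
OD450 rise of an inert dye (OrangeG) in control wells — a linear fit gives
a correction factor *c*(t) = 1 + β(t − t₀), exactly 1 at the first
timepoint — and for background via the mean OD600 of the same control
wells. Specific growth rates µ(t) come from rolling log-linear slopes; the
exponential phase is the longest window with r² ≥ 0.95 whose slope is
within 10% of the best window; µ_max comes from either the window slope or
a logistic fit OD(t) = K·N₀·e^{µt}/(K + N₀(e^{µt} − 1)). Media-only wells
that gain OD flag contamination.

**Exchange rates.** From single-time-point dilution series: ΔC = Y·X
(concentration change vs fresh medium against biomass at sampling), and
q = Y·µ in mmol gDCW⁻¹ h⁻¹, gated on n ≥ 3 points and r² > 0.8. OD
converts to biomass with organism-specific factors (2.06 gDW/L/OD for
*E. coli*, 3.62 *P. putida*, 3.31 *S. cerevisiae*).

**Quantification & energy charge.** Isotope-dilution quantification via
12C/13C ratios and linear calibrations; biomass normalization
c[µmol/gDCW] = c[µM]·10⁻³·V_recon[mL]/X[gDCW]; adenylate energy charge
EC = (ATP + ½ADP)/(ATP + ADP + AMP) as the quenching-quality readout.

**Plate QC.** Replicate CVs per feature with threshold fractions, proteome
coverage, robust-z outlier wells, contamination flags.

**Isotope labeling.** Theoretical isotopologue distributions of arbitrary
formulas, natural-abundance correction matrices for TBDMS-derivatized
amino-acid fragments (library shipped), MDV correction by nonnegative
least squares, and mol% comparison statistics.

**Simulation.** `simulate_plate()`, `simulate_exo_series()`,
`simulate_labeled_mdvs()` and `simulate_feature_matrix()` generate
complete synthetic experiments with known ground truth for every stage.

## Worked example

Simulate a plate of 80 *E. coli* replicates at a true growth rate of
0.594 h⁻¹ with 1%/h evaporation and 2% reading noise, then run the full
growth pipeline:

```r
library(plateomics)

sim <- simulate_plate(seed = 1, mu_true = c("E. coli" = 0.594))
res <- analyze_growth(sim$readings, sim$layout)

res$volume_loss
#> Volume-loss fit (4 dye wells): slope 0.0106 h^-1, r2 0.9276, t0 0.00 h
res$summary[c("n_sample_wells", "mu_mean", "mu_sd", "contaminated")]
#> # A tibble: 1 × 4
#>   n_sample_wells mu_mean  mu_sd contaminated
#>            <int>   <dbl>  <dbl> <lgl>
#> 1             80   0.599 0.0211 FALSE
```

The dye wells recover the simulated 1%/h volume loss, and the plate mean
µ_max lands within 1% of the generator truth with a between-well SD of
0.021 h⁻¹ — the reproducibility plate screens typically report.

Exchange rates from a noisy dilution series:

```r
exo <- simulate_exo_series(seed = 1, yields = c(glucose = -10, acetate = 4),
                           mu = 0.6, noise_cv = 0.05)
exchange_rate_table(exo$concentrations, exo$layout, exo$growth,
                    medium = tibble::tibble(compound = "glucose", conc_mm = 22.2))
#>   compound slope    r2     q direction passed
#> 1 acetate   4.14 0.991  2.48 secretion TRUE
#> 2 glucose  -9.38 0.998 -5.63 uptake    TRUE
```

Slopes are yields in mmol/gDCW; multiplying by µ gives q, so the true
rates here are −6.0 (glucose uptake) and +2.4 (acetate secretion)
mmol gDCW⁻¹ h⁻¹. Both pass the r² gate. And the quenching-quality
statistic:

```r
energy_charge(atp = 2.8, adp = 0.9, amp = 0.2)
#> [1] 0.8333333
```

See `vignettes/plate-screen-analysis.Rmd` for the models, parameter
choices and limitations, and `inst/cli/plateomics.R` for a command-line
front end (`simulate`, `growth`, `rates`, `mdv` subcommands).

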