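---
title: "Quantifying protein interactions from 3-filter FRET populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein interactions from 3-filter FRET populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretquant)
```

## The measurement problem

Sensitized-emission ("3-filter") FRET records three intensities per cell or
pixel: the donor channel `D_da`, the raw FRET channel `F_da` (acceptor
emission under donor excitation) and the acceptor channel `A_da`. None of
these is an efficiency: the FRET channel is contaminated by spectral
bleed-through from both fluorophores, and the channels are in unrelated
detector units. fretquant implements a fully empirical normalization chain
that converts these signals into an apparent FRET efficiency per cell
(DFRET) and an acceptor:donor molar ratio, then fits the population to a
mass-action binding model.

The chain has three calibration stages, each tied to a control sample a
FRET experiment already carries:

1. **Bleed-through factors S1–S4** from donor-only and acceptor-only cells
   (`bleedthrough_factors()`): per-cell channel ratios, aggregated by the
   median. `correct_signals()` inverts the donor/acceptor channel mixing
   and `fret_c()` removes the FRET-channel contamination.
2. **Unit conversion factors C1, C2** from a covalent donor–acceptor tandem
   construct (`calibration_factors()`), whose transfer efficiency `E_ref`
   is measured independently by acceptor photobleaching (`bleach_controls()`,
   `bleach_efficiency()`). C1 rescales donor-channel units into
   FRET-channel units so that `DFRET = FRETc / (C1 * D_c + FRETc)` is a
   genuine efficiency; C2 does the same for the acceptor channel using the
   tandem's fixed 1:1 stoichiometry.
3. **Model fit** (`fit_interaction()`): per-cell abundances
   `don = D_c*C1 + FRETc` and `acc = A_c*C2` feed a law-of-mass-action
   prediction of DFRET whose three parameters — apparent affinity `Ka_app`,
   stoichiometry `z`, plateau efficiency `FRET_max` — are estimated by
   nonlinear least squares over the cell population.

The key assumption throughout is equilibrium binding of a single complex
species: `z` acceptors bind one donor as a pre-formed unit, so the model
cannot resolve affinities of sub-complexes, and multiples of the molar
ratio (e.g. 2:2 versus 1:1) are indistinguishable.

## Why DFRET and not FRETN or N_FRET

Both classical measures are computed for comparison (`normalize_cells()`
returns all four). On a titration of acceptor against fixed donor, the
bound donor fraction — and with it any true apparent efficiency — rises
monotonically to a plateau. N_FRET divides by `sqrt(D_c * A_c)`, so at
high acceptor excess the growing denominator wins and the measure declines
after an interior maximum; FRETN divides by the product and acquires
reciprocal-intensity-squared units, scattering strongly with expression
level. Neither can be fitted by a saturation model. The package's tests
assert exactly this qualitative contrast on noiseless titrations.

## The binding model and its numerics

For totals `don`, `acc` and parameters `Ka`, `z`, the complex concentration
is the root in `[0, min(don, acc/z)]` of

$$ K_a \, c^2 - (K_a\,don + K_a\,acc/z + 1)\,c + K_a\,don\,(acc/z) = 0. $$

The textbook root `(s - sqrt(s^2 - 4 Ka^2 don (acc/z))) / (2 Ka)` suffers
catastrophic cancellation at large `Ka` — precisely the regime of the
infinite-affinity control experiment. `complex_concentration()` therefore
evaluates the conjugate form

$$ c = \frac{2\,K_a\,don\,(acc/z)}{s + \sqrt{s^2 - 4 K_a^2\,don\,(acc/z)}},
   \qquad s = K_a\,don + K_a\,acc/z + 1, $$

which is exact in both the `Ka -> 0` and `Ka -> Inf` limits; the test suite
checks it against an independent bisection root finder to below 1e-9
relative error over wide random parameter ranges, including `Ka = 1e12`.
The discriminant is clamped at zero against roundoff; degenerate inputs
(`don = 0` or `acc = 0`) return `c = 0` exactly. `z` is treated as a
continuous parameter because the fit estimates it freely.

Channel synthesis (`simulate_channels()`) applies the measurement model:

```
D_da = don_free + complex*(1 - FRET_max) + (acc_free + z*complex)*S4
A_da = acc_free + z*complex + (don_free + complex*(1 - FRET_max))*S3
F_da = complex*FRET_max + S1*D_da + S2*A_da
```

At `z = 1` the acceptor terms reduce to the familiar `acc_free + complex`;
for `z != 1` the complex carries `z` acceptor fluorophores, which is what
keeps the generator and the fitted model mutually consistent.

One deliberate quirk is preserved: the FRET-channel bleed terms act on the
already mixed `D_da`/`A_da` rather than on pure fluorophore signals, so a
donor-only control shows `F_d / D_d = S1 + S2*S3`. This is not corrected
away, because the empirical calibration absorbs it exactly: factors
estimated from controls generated by this same model are "effective"
factors, and running them through the correction chain cancels the
second-order cross term to machine precision. The tests demonstrate this
self-consistency with all four factors nonzero — it is the reason a purely
empirical calibration needs no knowledge of the underlying optics.

## Acceptor photobleaching

`bleach_efficiency()` computes the efficiency from pre/post bleach pairs
with three corrections folded into one expression: donor
co-bleaching/photoactivation (`df`, signed), acceptor photoswitching into
the donor channel (`af`) and incomplete bleaching (the
`1 - A_post/A_pre` denominator, which rescales a partial bleach to the
full-bleach donor gain). `df` and `af` are estimated once per experiment
from single-fluorophore controls and applied to every ROI — the controls
measure instrument-and-fluorophore properties, not per-cell ones, and
per-cell estimation would only inject control noise into every sample.
The invariance of the recovered efficiency to bleach completeness
(0.1–1.0) and to artifact factors is asserted to 1e-10 on noiseless
synthetic series.

## Fitting choices

* **Parameterization.** `log10(Ka_app)` is fitted internally because
  apparent affinities span many orders of magnitude; estimates and
  standard errors are reported on the natural scale by the delta method
  (`SE_Ka = ln(10) * Ka * SE_log10Ka`).
* **Initialization.** `z0 = 1`; `FRET_max0` = 95th percentile of in-window
  DFRET (a robust plateau guess); `Ka0 = 1/median(don)`, the affinity at
  which half-saturation falls in the middle of the observed abundance
  range.
* **Bounds.** `z` in [0.05, 20], `FRET_max` in (0, 1],
  `log10(Ka_app)` in [−12, 12]; Levenberg–Marquardt with box constraints,
  `ftol = 1e-10`, `ptol = 1e-8`, at most 1000 iterations. Fits are
  deterministic given identical inputs.
* **Weighting.** Unweighted least squares over cells.
* **Window.** The fit is restricted to cells with acceptor:donor ratio in
  [0.2, 2] by default — around the stoichiometric point of a 1:1 complex,
  where the curve shape carries the parameter information. For suspected
  non-1:1 stoichiometry the window should be scaled around the expected
  ratio (e.g. [0.1, 1] for a two-donor trimer, `z = 0.5`); an interaction
  fitted against a badly placed window mostly sees the flat plateau or the
  linear base of the curve and returns inflated uncertainties.
* **Reporting.** Standard errors from the parameter covariance at the
  optimum; `t = estimate/SE`; two-sided p values on `n_used − 3` degrees
  of freedom, the conventional report of a three-parameter nonlinear
  least-squares fit.

A caution on `Ka_app`: it is relative (intensity units are arbitrary), so
only comparisons within one instrument setup are meaningful, and it is
estimable only inside the dynamic range where affinity visibly shapes the
curve. An effectively infinite affinity fits to a large `Ka_app` with a
very large standard error — the number is reported, but the uncertainty is
the message. Rescaling all intensities by `k` leaves `z` and `FRET_max`
invariant and scales `Ka_app` by `1/k` exactly; this is asserted in the
tests.

One labeling subtlety: the classical molar-ratio expression
`(D_c*C1 + FRETc)/(A_c*C2)` has the donor-derived abundance in the
numerator, i.e. it is numerically a donor:acceptor ratio.
`molar_ratio()` evaluates that expression as defined; the `ratio` column
that `normalize_cells()` produces — and that windows, curves and plots use
throughout — is the acceptor:donor ratio `acc/don`, the axis on which a
saturation curve rises to its plateau.

## What the synthetic generator emulates

`population_config()`/`generate_population()` model a transient
co-transfection series: five plasmid mass-ratio groups (5:1, 3:1, 1:1,
1:3, 1:5) shift the donor/acceptor balance while total mass is held
constant; per-cell expression is log-normal (default median 500 counts,
`sdlog` 0.8 — the order of heterogeneity transient transfection shows)
with donor/acceptor log-correlation 0.5 (plasmids co-enter cells);
channels follow the measurement model above; detection applies
multiplicative log-normal noise (default CV 5%), optional additive
Gaussian background (default SD 1% of the median intensity) and 12-bit
clipping at 4095 counts. `generate_controls()` produces matched
donor-only, acceptor-only and tandem populations; the tandem (default
`E_ref = 0.30`, a typical fusion-construct efficiency) is fully bound at
locked 1:1 abundance. The default in-range affinity is `Ka = 1/500` per
intensity unit, i.e. half-saturation at the median expression level.

The generator does **not** model optics (PSF, acquisition-time
photobleaching), cell biology (localization, endogenous competitors) or
detector nonlinearity beyond clipping. Passing recovery tests therefore
show that the *evaluation chain* is unbiased and self-consistent under
realistic heterogeneity and noise — not that any particular biological
system satisfies the single-complex equilibrium assumption.

## Known limitations

* **Additive background noise biases low-FRET populations.** The FRET
  channel signal scales with `FRET_max * complex`, so for a dim pair
  (`FRET_max ~ 0.08`) background noise of even 1% of the donor median is a
  large fraction of the FRET signal. Because DFRET is a concave function
  of the FRET-channel signal, this produces a systematic downward bias
  that cell gating cannot remove — only brighter signal or lower background
  can. The package's parameter-recovery validation is therefore stated
  under multiplicative noise (CV 10%) with detector clipping; with
  additive background included, recovered `FRET_max` for dim pairs drops
  below truth and `Ka_app` compensates upward. Users fitting dim FRET
  pairs should treat absolute `FRET_max` with corresponding caution.
* Equilibrium only — no kinetics; a single pre/post pair per bleach ROI.
* One complex species; sub-complex affinities and ratio multiples are not
  identifiable.
* `Ka_app` is relative; conversion to molar `Kd` would require the
  intracellular concentration calibration the method deliberately avoids.

## Problem sizes used in validation

The test suite runs the full pipeline at 5000 cells per population
(1000 per ratio group) with 20 seeds for the recovery checks, 1000 random
draws for the root-finder oracle, and 64×64 synthetic image stacks for the
pixelwise map checks; the whole suite completes in well under a minute on
one CPU. Recovery is asserted as the mean over seeds (estimator bias):
the per-seed spread of, e.g., `z` is its reported standard error (~3–5%
at these sizes), so single-seed estimates scatter accordingly.

```{r example, eval = FALSE}
cfg <- population_config(n_cells = 1000, ka = 1 / 500, z = 0.5,
                         fret_max = 0.116, noise_cv = 0.10,
                         background_sd = 0, seed = 42)
pop <- generate_population(cfg)
ctl <- generate_controls(cfg)
cal <- calibrate(ctl$donor_only, ctl$acceptor_only, ctl$tandem, e_ref = 0.3)
nc  <- normalize_cells(pop$cells, cal)
fit <- fit_interaction(nc, window = c(0.1, 1))
tidy(fit)
autoplot(fit)
```
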