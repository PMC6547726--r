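# fretquant

Quantitative evaluation of sensitized-emission (3-filter) FRET measurements
of living cells. Given background-corrected donor, raw-FRET and acceptor
channel intensities — per cell from flow cytometry or microscopy ROIs, or
per pixel from multi-channel TIFF stacks — the package computes a calibrated
apparent FRET efficiency (**DFRET**) and acceptor:donor molar ratio for
every cell, and then retro-fits the whole population to a law-of-mass-action
binding model to extract three physical descriptors of the interaction:

* **Ka_app** — the apparent association constant (relative affinity, in
  reciprocal intensity units; proportional to the true Ka within one
  instrument setup),
* **z** — the complex stoichiometry (acceptor molecules per donor molecule
  in the complex; 0.5 for a two-donor/one-acceptor trimer),
* **FRET_max** — the transfer efficiency at complete donor saturation (the
  saturation-curve plateau, set by fluorophore distance/orientation).

It is aimed at cell biologists quantifying protein–protein interactions
with genetically encoded FRET pairs (e.g. YFP → mCherry), where expression
levels vary cell to cell — the method turns that heterogeneity into the
titration series the fit needs.

## The model in brief

Spectral crosstalk is removed with four empirically measured bleed-through
factors (S1–S4 from donor-only and acceptor-only controls):

    D_c = (D_da − S4·A_da) / (1 − S3·S4)
    A_c = (A_da − S3·D_da) / (1 − S3·S4)
    FRETc = F_da − S1·D_c − S2·A_c

A covalent donor–acceptor tandem construct of independently known transfer
efficiency E_ref (measured by acceptor photobleaching, with correction for
donor co-bleaching `df`, acceptor photoswitching `af` and incomplete
bleaching) calibrates the channel units:

    C1 = FRETc·(1 − E_ref) / (E_ref·D_c)        (donor → FRET-channel units)
    C2 = (D_c·C1 + FRETc) / A_c                 (acceptor → FRET-channel units)

    DFRET = FRETc / (C1·D_c + FRETc)            (apparent FRET efficiency)

With per-cell abundances `don = D_c·C1 + FRETc` and `acc = A_c·C2`, the
population follows the mass-action equilibrium

    Ka = [complex] / ([don]_free · [acc/z]_free),
    DFRET = FRET_max · [complex] / [don]

and nonlinear least squares on (don, acc, DFRET) across the population
yields Ka_app, z and FRET_max with standard errors, t values and p values.

Classical normalizations FRETN (Gordon) and N_FRET (Xia) are computed
alongside for comparison; on a titration they peak and decline rather than
saturate, which is why they cannot be fitted to the binding model.

## Worked example

Simulate a trimeric interaction (two donor-tagged molecules per
acceptor-tagged molecule, z = 0.5) across a five-step plasmid-ratio series,
calibrate from synthetic controls, normalize and fit:

```r
library(fretquant)

cfg <- population_config(n_cells = 1000, ka = 1/500, z = 0.5,
                         fret_max = 0.116, noise_cv = 0.10,
                         background_sd = 0, seed = 42)
pop <- generate_population(cfg)
ctl <- generate_controls(cfg)
cal <- calibrate(ctl$donor_only, ctl$acceptor_only, ctl$tandem, e_ref = 0.3)
nc  <- normalize_cells(pop$cells, cal)
fit <- fit_interaction(nc, window = c(0.1, 1))
print(fit)
```

```
Mass-action fit of the DFRET saturation data
  2255 cells in acceptor:donor ratio window [0.1, 1]
          Estimate Std. Error t value Pr(>|t|)
Ka_app   2.108e-03  6.296e-05   33.48   <2e-16 ***
z        4.967e-01  9.766e-03   50.86   <2e-16 ***
FRET_max 1.137e-01  1.537e-03   73.95   <2e-16 ***
  residual std. error 0.006189 on 2252 degrees of freedom (converged, 7 iterations)
```

The fit recovers the generating truth: z ≈ 0.5 identifies the trimeric
stoichiometry, FRET_max ≈ 0.114 (truth 0.116) the plateau efficiency, and
Ka_app ≈ 2.1×10⁻³ (truth 2×10⁻³) the in-range affinity. `tidy(fit)`,
`glance(fit)` and `augment(fit)` give broom-style tables;
`autoplot(fit)` overlays observed and fitted DFRET against the
acceptor:donor ratio, and `plot_dfret_population(nc)` draws the per-cell
saturation scatter with its moving-average curve.

A command-line front end with subcommands
`simulate | synth | normalize | bleach | fit | map` is installed at
`system.file("scripts", "fret-tools.R", package = "fretquant")`.

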