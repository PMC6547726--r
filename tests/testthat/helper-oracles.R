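# Independent numeric oracle for the mass-action equilibrium: vectorized
# bisection of ka*(don - c)*(acc/z - c) - c = 0 on [0, min(don, acc/z)].
# f is strictly decreasing on that interval, so plain bisection converges;
# 200 halvings exhaust double precision.
bisect_complex <- function(don, acc, ka, z = 1, iterations = 200) {
  b <- acc / z
  lo <- rep(0, length(don))
  hi <- pmin(don, b)
  f <- function(c) ka * (don - c) * (b - c) - c
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    pos <- f(mid) > 0
    lo <- ifelse(pos, mid, lo)
    hi <- ifelse(pos, hi, mid)
  }
  (lo + hi) / 2
}

# Noiseless titration population at fixed donor over a log-spaced acceptor
# grid, as raw channel intensities plus an exact calibration, for tests that
# compare measures along a saturation series.
noiseless_titration <- function(don = 500, ratios = 10^seq(-2, log10(400), length.out = 120),
                                ka = 1 / 500, z = 1, fret_max = 0.3,
                                bleed = list(s1 = 0, s2 = 0, s3 = 0, s4 = 0)) {
  st <- complex_concentration(don, don * ratios, ka = ka, z = z)
  ch <- simulate_channels(st$don_free, st$acc_free, st$complex, fret_max,
    s1 = bleed$s1, s2 = bleed$s2, s3 = bleed$s3, s4 = bleed$s4, z = z
  )
  tibble::tibble(donor = ch$D_da, fret = ch$F_da, acceptor = ch$A_da)
}

# Exact calibration object (no estimation noise) for given bleed-through
# factors and tandem efficiency, via a small noiseless tandem population.
exact_calibration <- function(e_ref = 0.3, bleed = list(s1 = 0, s2 = 0, s3 = 0, s4 = 0)) {
  lvl <- c(200, 500, 1500)
  tandem <- simulate_channels(0, 0, lvl, e_ref,
    s1 = bleed$s1, s2 = bleed$s2, s3 = bleed$s3, s4 = bleed$s4
  )
  tandem <- tibble::tibble(
    donor = tandem$D_da, fret = tandem$F_da, acceptor = tandem$A_da
  )
  b <- structure(bleed, class = "bleedthrough_factors")
  td <- correct_signals(tandem, b)
  td$F_c <- fret_c(td$fret, td$D_c, td$A_c, b)
  structure(
    list(bleed = b, cal = calibration_factors(td, e_ref = e_ref)),
    class = "fret_calibration"
  )
}

# Full generate -> calibrate -> normalize -> fit pipeline under the stated
# recovery conditions (multiplicative noise only, 12-bit detector).
recovery_pipeline <- function(seed, z = 1, fret_max = 0.3, ka = 1 / 500,
                              n_cells = 1000, noise_cv = 0.1,
                              window = c(0.2, 2), bit_depth = 12) {
  cfg <- population_config(
    n_cells = n_cells, ka = ka, z = z, fret_max = fret_max,
    noise_cv = noise_cv, background_sd = 0, bit_depth = bit_depth, seed = seed
  )
  pop <- generate_population(cfg)
  ctl <- generate_controls(cfg)
  cal <- calibrate(ctl$donor_only, ctl$acceptor_only, ctl$tandem,
    e_ref = cfg$tandem_e
  )
  fit_interaction(normalize_cells(pop$cells, cal), window = window)
}
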