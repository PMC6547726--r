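test_that("bleed-through factors are per-cell control ratios with median aggregation", {
  d <- tibble::tibble(donor = 1000, fret = 250, acceptor = 0)
  a <- tibble::tibble(donor = 0, fret = 100, acceptor = 1000)
  bt <- bleedthrough_factors(d, a)
  expect_equal(bt$s1, 0.25)
  expect_equal(bt$s2, 0.1)
  expect_equal(bt$s3, 0)
  expect_equal(bt$s4, 0)

  # crosstalk-free fluorophores give all-zero factors
  d0 <- tibble::tibble(donor = c(500, 900), fret = 0, acceptor = 0)
  a0 <- tibble::tibble(donor = 0, fret = 0, acceptor = c(400, 800))
  expect_equal(unlist(unclass(bleedthrough_factors(d0, a0))),
    c(s1 = 0, s2 = 0, s3 = 0, s4 = 0))

  # median is robust to a single aberrant control cell
  d_out <- tibble::tibble(
    donor = c(1000, 1000, 1000), fret = c(250, 250, 9000), acceptor = 0
  )
  expect_equal(bleedthrough_factors(d_out, a)$s1, 0.25)

  expect_error(
    bleedthrough_factors(tibble::tibble(donor = 0, fret = 0, acceptor = 0), a),
    "positive"
  )
})

test_that("signal correction inverts the two-channel crosstalk mixing", {
  b0 <- structure(list(s1 = 0, s2 = 0, s3 = 0, s4 = 0),
    class = "bleedthrough_factors")
  cells <- tibble::tibble(donor = c(500, 0), fret = 0, acceptor = c(800, 0))
  cs <- correct_signals(cells, b0)
  expect_equal(cs$D_c, c(500, 0))
  expect_equal(cs$A_c, c(800, 0))

  b <- structure(list(s1 = 0, s2 = 0, s3 = 0.1, s4 = 0.2),
    class = "bleedthrough_factors")
  cs <- correct_signals(tibble::tibble(donor = 1000, fret = 0, acceptor = 1000), b)
  expect_equal(cs$D_c, 800 / 0.98)
  expect_equal(cs$A_c, 900 / 0.98)

  bad <- structure(list(s1 = 0, s2 = 0, s3 = 1, s4 = 1.2),
    class = "bleedthrough_factors")
  expect_error(correct_signals(cells, bad), "Singular")
})

test_that("FRETc subtracts the bleed-through estimated from corrected signals", {
  b <- list(s1 = 0.25, s2 = 0.1)
  expect_equal(fret_c(500, 1000, 1000, b), 150)
  # pure-bleed non-interacting cell
  expect_equal(fret_c(0.25 * 1000 + 0.1 * 800, 1000, 800, b), 0)
  expect_equal(fret_c(42, 1000, 800, list(s1 = 0, s2 = 0)), 42)
})

test_that("FRETN and N_FRET follow their defining scaling laws", {
  expect_equal(fretn(150, 1000, 1000, g = 1), 1.5e-4)
  expect_equal(fretn(0, 1000, 1000), 0)
  # doubling both signals at fixed FRETc quarters FRETN
  expect_equal(fretn(150, 2000, 2000), 1.5e-4 / 4)
  expect_error(fretn(1, 0, 10), "undefined")

  expect_equal(n_fret(150, 1000, 1000), 0.15)
  expect_equal(n_fret(0, 1000, 1000), 0)
  # N_FRET is invariant to a common intensity rescaling
  k <- 7.3
  expect_equal(n_fret(150 * k, 1000 * k, 1000 * k), 0.15)
  expect_error(n_fret(1, 10, 0), "undefined")
})

test_that("C1/C2 derivation reproduces the tandem-construct algebra", {
  td <- tibble::tibble(D_c = 0.65, F_c = 0.35, A_c = 1)
  cal <- calibration_factors(td, e_ref = 0.35)
  expect_equal(cal$c1, 1)
  expect_equal(cal$c2, 1)
  expect_error(calibration_factors(td, e_ref = 1.2), "in \\(0, 1\\)")
  expect_error(calibration_factors(td, e_ref = 0), "in \\(0, 1\\)")
})

test_that("DFRET and molar ratio evaluate their defining expressions", {
  expect_equal(dfret(150, 1000, c1 = 1), 150 / 1150)
  expect_equal(dfret(0, 1000, c1 = 1), 0)
  expect_error(dfret(150, 1000, c1 = 0), "positive")

  expect_equal(molar_ratio(2000, 0, 1000, c1 = 1, c2 = 1), 2)
  # homogeneity: common scale factor cancels
  expect_equal(molar_ratio(2000 * 3, 0, 1000 * 3, 1, 1), 2)
  expect_error(molar_ratio(1, 1, 0, 1, 1), "undefined")
})

test_that("tandem round trip: calibration and DFRET are mutually inverse", {
  # nonzero crosstalk in all four factors, noiseless tandem population
  bleed <- list(s1 = 0.25, s2 = 0.1, s3 = 0.05, s4 = 0.02)
  e_star <- 0.3
  lvl <- c(100, 300, 900, 2700)
  ch <- simulate_channels(0, 0, lvl, e_star,
    s1 = bleed$s1, s2 = bleed$s2, s3 = bleed$s3, s4 = bleed$s4
  )
  tandem <- tibble::tibble(donor = ch$D_da, fret = ch$F_da, acceptor = ch$A_da)
  cal <- calibrate(
    donor_only = tibble::tibble(
      donor = 1000, fret = 250, acceptor = 50
    ),
    acceptor_only = tibble::tibble(
      donor = 20, fret = 100, acceptor = 1000
    ),
    tandem = tandem, e_ref = e_star
  )
  nc <- normalize_cells(tandem, cal)
  expect_equal(nc$DFRET, rep(e_star, length(lvl)), tolerance = 1e-10)
  expect_equal(nc$ratio, rep(1, length(lvl)), tolerance = 1e-10)
  expect_equal(
    molar_ratio(nc$D_c, nc$FRETc, nc$A_c, cal$cal$c1, cal$cal$c2),
    rep(1, length(lvl)),
    tolerance = 1e-10
  )
})

test_that("normalized measures are invariant to cell order", {
  cal <- exact_calibration(e_ref = 0.3)
  cells <- noiseless_titration(fret_max = 0.3)
  perm <- sample(nrow(cells))
  a <- normalize_cells(cells, cal)
  b <- normalize_cells(cells[perm, ], cal)
  expect_equal(a$DFRET[perm], b$DFRET)
  expect_equal(a$ratio[perm], b$ratio)
})

test_that("on a titration DFRET saturates monotonically while N_FRET peaks and declines", {
  cal <- exact_calibration(e_ref = 0.3)
  nc <- normalize_cells(noiseless_titration(fret_max = 0.3), cal)
  nc <- nc[order(nc$ratio), ]
  expect_true(all(diff(nc$DFRET) >= -1e-12))
  expect_equal(max(nc$DFRET), 0.3, tolerance = 1e-2)
  # interior maximum of N_FRET: slope changes sign
  slopes <- diff(nc$N_FRET)
  peak <- which.max(nc$N_FRET)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(nc))
  expect_lt(slopes[length(slopes)], 0)
  expect_gt(slopes[1], 0)
})

test_that("FRETc of single-fluorophore cells is zero under empirically estimated factors", {
  # the FRET-channel bleed acts on the mixed channel signals, so the factors
  # estimated from single-color controls are "effective" ones (S1 + S2*S3,
  # S2 + S1*S4) that cancel the second-order cross term exactly
  bleed <- list(s1 = 0.25, s2 = 0.1, s3 = 0.05, s4 = 0.02)
  mk <- function(don, acc) {
    ch <- simulate_channels(don, acc, 0, 0.3,
      s1 = bleed$s1, s2 = bleed$s2, s3 = bleed$s3, s4 = bleed$s4
    )
    tibble::tibble(donor = ch$D_da, fret = ch$F_da, acceptor = ch$A_da)
  }
  donor_only <- mk(c(200, 800), 0)
  acceptor_only <- mk(0, c(200, 800))
  bt <- bleedthrough_factors(donor_only, acceptor_only)
  expect_equal(bt$s1, bleed$s1 + bleed$s2 * bleed$s3)
  expect_equal(bt$s2, bleed$s2 + bleed$s1 * bleed$s4)
  expect_equal(bt$s3, bleed$s3)
  expect_equal(bt$s4, bleed$s4)
  for (cells in list(donor_only, acceptor_only)) {
    cs <- correct_signals(cells, bt)
    expect_equal(fret_c(cs$fret, cs$D_c, cs$A_c, bt), c(0, 0), tolerance = 1e-12)
  }
  # and a mixed interacting sample corrects to the pure sensitized emission
  st <- complex_concentration(500, 700, ka = 0.01)
  ch <- simulate_channels(st$don_free, st$acc_free, st$complex, 0.3,
    s1 = bleed$s1, s2 = bleed$s2, s3 = bleed$s3, s4 = bleed$s4
  )
  cs <- correct_signals(
    tibble::tibble(donor = ch$D_da, fret = ch$F_da, acceptor = ch$A_da), bt
  )
  expect_equal(fret_c(cs$fret, cs$D_c, cs$A_c, bt), st$complex * 0.3,
    tolerance = 1e-10)
})

test_that("moving-average curve is flat for constant DFRET and raw for window 1", {
  cells <- tibble::tibble(ratio = runif(40, 0.1, 5), DFRET = 0.2)
  curve <- aggregate_curve(cells, window = 7)
  expect_equal(curve$DFRET, rep(0.2, 40))

  raw <- aggregate_curve(cells, window = 1)
  expect_equal(raw$ratio, sort(cells$ratio))

  # noiseless simulated population follows the theoretical saturation curve
  cal <- exact_calibration(e_ref = 0.3)
  nc <- normalize_cells(noiseless_titration(fret_max = 0.3, ka = 1 / 500), cal)
  curve <- aggregate_curve(nc, window = 5)
  theo <- saturation_curve(
    don = 500, acc_grid = curve$ratio * 500, ka = 1 / 500, fret_max = 0.3
  )
  expect_equal(curve$DFRET, theo$efficiency, tolerance = 0.02)
})

test_that("gating removes cells below the inclusion floor", {
  cells <- tibble::tibble(D_c = c(5, 50, 500), A_c = c(500, 5, 300))
  expect_equal(nrow(gate_cells(cells, floor = 10)), 1)
  expect_equal(nrow(gate_cells(cells, floor = 0)), 3)
})
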