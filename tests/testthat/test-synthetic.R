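test_that("generation is deterministic under a fixed seed", {
  cfg <- population_config(n_cells = 50, seed = 123)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_controls(cfg), generate_controls(cfg))
  expect_identical(
    generate_bleach_series(n = 5, noise_cv = 0.05, seed = 4),
    generate_bleach_series(n = 5, noise_cv = 0.05, seed = 4)
  )
})

test_that("population structure follows the transfection-series design", {
  cfg <- population_config(n_cells = 40, seed = 1)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop$cells), 40 * 5)
  expect_equal(length(unique(pop$cells$group)), 5)
  expect_true(all(pop$cells$donor >= 0 & pop$cells$donor <= 4095))
  # acceptor-rich groups have higher acceptor:donor truth ratios
  med <- tapply(pop$truth$acc_total / pop$truth$don_total, pop$truth$group,
    median)
  expect_gt(med[["1:5"]], med[["5:1"]])
  # ground truth satisfies the binding model it was generated from
  st <- complex_concentration(pop$truth$don_total, pop$truth$acc_total,
    ka = cfg$ka, z = cfg$z)
  expect_equal(pop$truth$complex, st$complex)
})

test_that("noiseless tandem-mode cells all show DFRET equal to the tandem efficiency", {
  cfg <- population_config(
    n_cells = 60, noise_cv = 0, background_sd = 0, bit_depth = Inf,
    tandem_e = 0.3, seed = 17
  )
  ctl <- generate_controls(cfg)
  cal <- calibrate(ctl$donor_only, ctl$acceptor_only, ctl$tandem, e_ref = 0.3)
  nc <- normalize_cells(ctl$tandem, cal)
  expect_equal(nc$DFRET, rep(0.3, 60), tolerance = 1e-10)
  expect_equal(nc$ratio, rep(1, 60), tolerance = 1e-10)
})

test_that("control populations expose only the configured crosstalk", {
  bleed <- list(s1 = 0.25, s2 = 0.1, s3 = 0.05, s4 = 0.02)
  cfg <- population_config(
    n_cells = 100, bleed = bleed, noise_cv = 0, background_sd = 0,
    bit_depth = Inf, seed = 8
  )
  ctl <- generate_controls(cfg)
  # donor-only: acceptor channel is exactly S3 * donor channel signal
  # (donor-channel signal itself is pure donor when no acceptor is present)
  expect_equal(ctl$donor_only$acceptor / ctl$donor_only$donor,
    rep(bleed$s3, 100))
  expect_equal(ctl$acceptor_only$donor / ctl$acceptor_only$acceptor,
    rep(bleed$s4, 100))
  bt <- bleedthrough_factors(ctl$donor_only, ctl$acceptor_only)
  # estimated FRET-channel factors are the effective ones (see normalization
  # tests); the donor/acceptor channel factors are recovered exactly
  expect_equal(bt$s1, bleed$s1 + bleed$s2 * bleed$s3, tolerance = 1e-12)
  expect_equal(bt$s2, bleed$s2 + bleed$s1 * bleed$s4, tolerance = 1e-12)
  expect_equal(bt$s3, bleed$s3, tolerance = 1e-12)
  expect_equal(bt$s4, bleed$s4, tolerance = 1e-12)
})

test_that("crosstalk estimated from noisy controls matches configuration within noise", {
  bleed <- list(s1 = 0.25, s2 = 0.1, s3 = 0.05, s4 = 0.02)
  cfg <- population_config(
    n_cells = 2000, bleed = bleed, noise_cv = 0.05, seed = 31
  )
  ctl <- generate_controls(cfg)
  bt <- bleedthrough_factors(ctl$donor_only, ctl$acceptor_only)
  expect_equal(bt$s1, bleed$s1 + bleed$s2 * bleed$s3, tolerance = 0.02)
  expect_equal(bt$s2, bleed$s2 + bleed$s1 * bleed$s4, tolerance = 0.05)
  expect_equal(bt$s3, bleed$s3, tolerance = 0.05)
  expect_equal(bt$s4, bleed$s4, tolerance = 0.15)
})

test_that("tandem calibration reproduces the generator's unit conversions", {
  # noiseless generator uses identical units in all channels, so calibrating
  # against the generating efficiency must give C1 = C2 = 1
  cfg <- population_config(
    n_cells = 50, noise_cv = 0, background_sd = 0, bit_depth = Inf, seed = 5
  )
  ctl <- generate_controls(cfg)
  cal <- calibrate(ctl$donor_only, ctl$acceptor_only, ctl$tandem, e_ref = 0.3)
  expect_equal(cal$cal$c1, 1, tolerance = 1e-12)
  expect_equal(cal$cal$c2, 1, tolerance = 1e-12)
})

test_that("detector model clips to the configured bit depth", {
  cfg <- population_config(
    n_cells = 500, median_intensity = 4000, sdlog = 1, seed = 3
  )
  pop <- generate_population(cfg)
  expect_true(all(pop$cells$donor <= 4095))
  expect_true(any(pop$cells$donor == 4095))
  expect_true(all(pop$cells$fret >= 0))
})

test_that("synthetic image stacks carry per-region model values and ground truth", {
  img <- generate_image_stack(
    width = 40, height = 40,
    regions = tibble::tibble(x = 20, y = 20, radius = 10,
      don = 1500, acc = 1500),
    ka = 1 / 500, fret_max = 0.3, noise_cv = 0, bit_depth = Inf
  )
  expect_equal(dim(img$stack), c(40, 40, 3))
  # uniform region: one distinct efficiency value inside the mask
  vals <- unique(img$efficiency[img$mask])
  expect_length(vals, 1)
  st <- complex_concentration(1500, 1500, ka = 1 / 500)
  expect_equal(vals, apparent_efficiency(st$complex, 1500, 0.3))
  # background carries no truth
  expect_true(all(is.na(img$efficiency[!img$mask])))
  expect_true(all(img$stack[, , 1][!img$mask] == 0))

  # two regions with different acceptor:donor ratios are ordered like the
  # saturation curve
  img2 <- generate_image_stack(noise_cv = 0, bit_depth = Inf)
  effs <- sort(unique(img2$efficiency[img2$mask]))
  expect_length(effs, 2)
  curve <- saturation_curve(1500, c(300, 1500), ka = 1 / 500, fret_max = 0.3)
  expect_equal(effs, sort(curve$efficiency))
})
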