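#' Configuration for synthetic FRET cell populations
#'
#' Collects the parameters describing a simulated transient co-transfection
#' experiment. Expression per cell is heterogeneous and log-normal, with
#' donor and acceptor log-levels correlated within a cell (co-transfection),
#' and a series of transfection groups shifts the mean acceptor:donor
#' balance the way plasmid mass ratios do. Channels are synthesized from the
#' mass-action binding equilibrium and carry multiplicative (log-normal)
#' detection noise, additive Gaussian background noise and 12-bit detector
#' clipping.
#'
#' @param n_cells Cells per transfection group (>= 1).
#' @param plasmid_ratios Donor:acceptor plasmid mass ratios of the
#'   transfection series, as donor/acceptor quotients. Default `5:1, 3:1,
#'   1:1, 1:3, 1:5`.
#' @param median_intensity Median expression level per channel (arbitrary
#'   intensity units) for a balanced 1:1 transfection.
#' @param sdlog Dispersion of the log-normal expression distribution
#'   (natural-log sd).
#' @param correlation Correlation of donor and acceptor log-expression
#'   within a cell.
#' @param ka Apparent association constant of the simulated pair, in
#'   reciprocal intensity units.
#' @param z Stoichiometry factor (acceptors per donor in the complex).
#' @param fret_max Maximal FRET efficiency of the simulated pair.
#' @param tandem_e Transfer efficiency of the tandem calibration construct.
#' @param bleed Named list `s1`, `s2`, `s3`, `s4` of bleed-through factors.
#'   Default all 0 (the simplification under which the binding model is
#'   exact; nonzero values exercise the correction chain).
#' @param noise_cv Multiplicative noise coefficient of variation per channel.
#' @param background_sd Additive background noise SD; default 1% of the
#'   median intensity.
#' @param bit_depth Detector bit depth; intensities are clipped to
#'   `[0, 2^bit_depth - 1]`. Use `Inf` to disable clipping.
#' @param seed Integer seed for reproducible generation.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_cells = 1000,
                              plasmid_ratios = c(5, 3, 1, 1 / 3, 1 / 5),
                              median_intensity = 500,
                              sdlog = 0.8,
                              correlation = 0.5,
                              ka = 1 / 500,
                              z = 1,
                              fret_max = 0.3,
                              tandem_e = 0.3,
                              bleed = list(s1 = 0, s2 = 0, s3 = 0, s4 = 0),
                              noise_cv = 0.05,
                              background_sd = NULL,
                              bit_depth = 12,
                              seed = NULL) {
  if (n_cells < 1) stop("`n_cells` must be >= 1.", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0.", call. = FALSE)
  if (abs(correlation) > 1) stop("`correlation` must be in [-1, 1].", call. = FALSE)
  stop_if_bad_parameter(ka, "ka")
  stop_if_bad_parameter(z, "z")
  if (fret_max < 0 || fret_max > 1) stop("`fret_max` must be in [0, 1].", call. = FALSE)
  if (is.null(background_sd)) background_sd <- 0.01 * median_intensity
  structure(
    list(
      n_cells = as.integer(n_cells),
      plasmid_ratios = plasmid_ratios,
      median_intensity = median_intensity,
      sdlog = sdlog,
      correlation = correlation,
      ka = ka, z = z, fret_max = fret_max, tandem_e = tandem_e,
      bleed = bleed,
      noise_cv = noise_cv,
      background_sd = background_sd,
      max_count = if (is.finite(bit_depth)) 2^bit_depth - 1 else Inf,
      seed = seed
    ),
    class = "population_config"
  )
}

# Correlated bivariate log-normal expression draw: one column per fluorophore.
draw_expression <- function(n, meanlog_d, meanlog_a, sdlog, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(
    exp(meanlog_d + sdlog * z1),
    exp(meanlog_a + sdlog * z2)
  )
}

# Multiplicative log-normal noise with unit mean and given CV, plus additive
# Gaussian background, then detector clipping.
apply_detector <- function(x, cfg) {
  if (cfg$noise_cv > 0) {
    sdl <- sqrt(log(1 + cfg$noise_cv^2))
    x <- x * exp(stats::rnorm(length(x), mean = -sdl^2 / 2, sd = sdl))
  }
  if (cfg$background_sd > 0) {
    x <- x + stats::rnorm(length(x), sd = cfg$background_sd)
  }
  pmin(pmax(x, 0), cfg$max_count)
}

#' Generate a synthetic co-transfection cell population
#'
#' Draws per-cell total donor and acceptor abundances for each transfection
#' group, solves the binding equilibrium per cell, synthesizes the three
#' detection channels and applies the detector model. Ground truth is
#' retained for parameter-recovery tests.
#'
#' @param cfg A [population_config()].
#' @return A list with `cells` (tibble: `id`, `group` plasmid-ratio label,
#'   `donor`, `fret`, `acceptor` measured intensities) and `truth` (tibble:
#'   `id`, `group`, `don_total`, `acc_total`, `complex`, `efficiency`).
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "population_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  groups <- purrr::imap(cfg$plasmid_ratios, function(r, i) {
    # keep total plasmid mass constant across groups
    d_scale <- 2 * r / (1 + r)
    a_scale <- 2 / (1 + r)
    ex <- draw_expression(
      cfg$n_cells,
      meanlog_d = log(cfg$median_intensity * d_scale),
      meanlog_a = log(cfg$median_intensity * a_scale),
      sdlog = cfg$sdlog, rho = cfg$correlation
    )
    st <- complex_concentration(ex[, 1], ex[, 2], ka = cfg$ka, z = cfg$z)
    ch <- simulate_channels(
      st$don_free, st$acc_free, st$complex,
      fret_max = cfg$fret_max,
      s1 = cfg$bleed$s1, s2 = cfg$bleed$s2,
      s3 = cfg$bleed$s3, s4 = cfg$bleed$s4,
      z = cfg$z
    )
    label <- format_ratio_label(r)
    list(
      cells = tibble::tibble(
        group = label,
        donor = apply_detector(ch$D_da, cfg),
        fret = apply_detector(ch$F_da, cfg),
        acceptor = apply_detector(ch$A_da, cfg)
      ),
      truth = tibble::tibble(
        group = label,
        don_total = st$don,
        acc_total = st$acc,
        complex = st$complex,
        efficiency = apparent_efficiency(st$complex, st$don, cfg$fret_max)
      )
    )
  })
  cells <- dplyr::bind_rows(purrr::map(groups, "cells"))
  truth <- dplyr::bind_rows(purrr::map(groups, "truth"))
  cells <- dplyr::mutate(cells, id = dplyr::row_number(), .before = 1)
  truth <- dplyr::mutate(truth, id = dplyr::row_number(), .before = 1)
  list(cells = cells, truth = truth)
}

format_ratio_label <- function(r) {
  if (r >= 1) paste0(round(r, 2), ":1") else paste0("1:", round(1 / r, 2))
}

#' Generate synthetic calibration control populations
#'
#' Produces the three control samples the calibration workflow needs:
#' donor-only and acceptor-only populations (bleed-through signal only) and
#' a tandem-construct population with locked 1:1 abundance and transfer
#' efficiency `cfg$tandem_e` (every molecule in a "complex": the covalent
#' fusion cannot dissociate).
#'
#' @param cfg A [population_config()].
#' @param n Cells per control population; defaults to `cfg$n_cells`.
#' @return A list of tibbles `donor_only`, `acceptor_only`, `tandem`, each
#'   with columns `donor`, `fret`, `acceptor`.
#' @export
generate_controls <- function(cfg, n = cfg$n_cells) {
  stopifnot(inherits(cfg, "population_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  lvl <- function(n) stats::rlnorm(n, log(cfg$median_intensity), cfg$sdlog)
  b <- cfg$bleed

  d <- lvl(n)
  donor_only <- simulate_channels(d, 0, 0, cfg$fret_max,
    s1 = b$s1, s2 = b$s2, s3 = b$s3, s4 = b$s4
  )
  a <- lvl(n)
  acceptor_only <- simulate_channels(0, a, 0, cfg$fret_max,
    s1 = b$s1, s2 = b$s2, s3 = b$s3, s4 = b$s4
  )
  t <- lvl(n)
  tandem <- simulate_channels(0, 0, t, cfg$tandem_e,
    s1 = b$s1, s2 = b$s2, s3 = b$s3, s4 = b$s4, z = 1
  )

  as_cells <- function(ch) {
    tibble::tibble(
      donor = apply_detector(ch$D_da, cfg),
      fret = apply_detector(ch$F_da, cfg),
      acceptor = apply_detector(ch$A_da, cfg)
    )
  }
  list(
    donor_only = as_cells(donor_only),
    acceptor_only = as_cells(acceptor_only),
    tandem = as_cells(tandem)
  )
}

#' Generate a synthetic acceptor-photobleaching series
#'
#' Constructs pre/post intensity records whose artifact- and
#' completeness-corrected bleaching efficiency equals `true_e` exactly in
#' the noiseless case. For each ROI the unquenched donor level `D0` is
#' drawn log-normally; before bleaching the donor reads `D0 * (1 - true_e)`
#' and after bleaching a fraction `bleach_fraction` of acceptors the donor
#' gains the de-quenched emission `bleach_fraction * true_e * D0`, modified
#' by the donor co-bleaching factor `df` and the acceptor photoswitching
#' contribution `af * (A_pre - A_post)`.
#'
#' @param n Number of sample ROIs (and of records per control).
#' @param true_e True FRET efficiency of the sample, in `[0, 1)`.
#' @param bleach_fraction Fraction of acceptor fluorescence destroyed by the
#'   bleach pulse, in (0, 1].
#' @param df Donor co-bleach/photoactivation factor (signed).
#' @param af Acceptor photoswitching factor.
#' @param median_intensity Median unquenched donor intensity.
#' @param acceptor_scale Acceptor pre-bleach intensity per unit donor.
#' @param noise_cv Multiplicative noise CV applied to every stored
#'   intensity; 0 gives exact records.
#' @param seed Integer seed.
#' @return A list of tibbles: `records` (sample, columns `D_pre`, `D_post`,
#'   `A_pre`, `A_post`), `donor_only` and `acceptor_only` controls with the
#'   column layout [bleach_controls()] expects, and `truth` (per-ROI `D0`).
#' @export
generate_bleach_series <- function(n = 20,
                                   true_e = 0.3,
                                   bleach_fraction = 1,
                                   df = 0,
                                   af = 0,
                                   median_intensity = 1000,
                                   acceptor_scale = 1,
                                   noise_cv = 0,
                                   seed = NULL) {
  if (true_e < 0 || true_e >= 1) stop("`true_e` must be in [0, 1).", call. = FALSE)
  if (bleach_fraction <= 0 || bleach_fraction > 1) {
    stop("`bleach_fraction` must be in (0, 1].", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  noisy <- function(x) {
    if (noise_cv <= 0) {
      x
    } else {
      sdl <- sqrt(log(1 + noise_cv^2))
      x * exp(stats::rnorm(length(x), -sdl^2 / 2, sdl))
    }
  }

  d0 <- stats::rlnorm(n, log(median_intensity), 0.3)
  a_pre <- acceptor_scale * d0
  a_post <- (1 - bleach_fraction) * a_pre
  d_pre <- d0 * (1 - true_e)
  d_post <- d_pre * (1 + df) + af * (a_pre - a_post) +
    bleach_fraction * true_e * d0
  records <- tibble::tibble(
    D_pre = noisy(d_pre), D_post = noisy(d_post),
    A_pre = noisy(a_pre), A_post = noisy(a_post)
  )

  dc0 <- stats::rlnorm(n, log(median_intensity), 0.3)
  donor_only <- tibble::tibble(
    D_pre = noisy(dc0),
    D_post = noisy(dc0 * (1 + df))
  )
  ac_a <- stats::rlnorm(n, log(median_intensity * acceptor_scale), 0.3)
  ac_a_post <- (1 - bleach_fraction) * ac_a
  ac_d <- 0.05 * ac_a # residual acceptor bleed into the donor channel
  acceptor_only <- tibble::tibble(
    D_pre = noisy(ac_d),
    D_post = noisy(ac_d + af * (ac_a - ac_a_post)),
    A_pre = noisy(ac_a),
    A_post = noisy(ac_a_post)
  )
  list(
    records = records,
    donor_only = donor_only,
    acceptor_only = acceptor_only,
    truth = tibble::tibble(D0 = d0, true_e = true_e)
  )
}

#' Render a synthetic three-channel FRET image stack
#'
#' Draws disc-shaped "cells" with per-region total donor and acceptor
#' abundances on a dark background, computes the binding equilibrium per
#' region, synthesizes the three channels per pixel and quantizes to the
#' detector bit depth. Ground truth (efficiency map, foreground mask) is
#' returned for pixelwise round-trip tests.
#'
#' @param width,height Image dimensions in pixels.
#' @param regions Data frame with one row per cell region and columns `x`,
#'   `y`, `radius` (pixels), `don`, `acc` (total abundances in intensity
#'   units).
#' @param ka,z,fret_max Binding parameters of the imaged pair.
#' @param bleed Named list `s1`..`s4`.
#' @param noise_cv Multiplicative per-pixel noise CV.
#' @param background Constant background offset added to every channel.
#' @param bit_depth Detector bit depth (`Inf` to skip quantization).
#' @param seed Integer seed.
#' @return A list with `stack` (array `height x width x 3`, channels donor,
#'   fret, acceptor), `efficiency` (matrix of true apparent efficiency, NA
#'   on background) and `mask` (logical foreground matrix).
#' @export
generate_image_stack <- function(width = 64, height = 64,
                                 regions = tibble::tibble(
                                   x = c(20, 44), y = c(32, 32),
                                   radius = c(12, 12),
                                   don = c(1500, 1500), acc = c(1500, 300)
                                 ),
                                 ka = 1 / 500, z = 1, fret_max = 0.3,
                                 bleed = list(s1 = 0, s2 = 0, s3 = 0, s4 = 0),
                                 noise_cv = 0,
                                 background = 0,
                                 bit_depth = 12,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stack <- array(background, dim = c(height, width, 3))
  eff <- matrix(NA_real_, height, width)
  mask <- matrix(FALSE, height, width)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)

  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    inside <- (xs - rg$x)^2 + (ys - rg$y)^2 <= rg$radius^2
    st <- complex_concentration(rg$don, rg$acc, ka = ka, z = z)
    ch <- simulate_channels(
      st$don_free, st$acc_free, st$complex, fret_max,
      s1 = bleed$s1, s2 = bleed$s2, s3 = bleed$s3, s4 = bleed$s4, z = z
    )
    stack[, , 1][inside] <- background + ch$D_da
    stack[, , 2][inside] <- background + ch$F_da
    stack[, , 3][inside] <- background + ch$A_da
    eff[inside] <- apparent_efficiency(st$complex, st$don, fret_max)
    mask <- mask | inside
  }
  if (noise_cv > 0) {
    sdl <- sqrt(log(1 + noise_cv^2))
    stack <- stack * exp(stats::rnorm(length(stack), -sdl^2 / 2, sdl))
  }
  max_count <- if (is.finite(bit_depth)) 2^bit_depth - 1 else Inf
  if (is.finite(max_count)) {
    stack <- pmin(pmax(round(stack), 0), max_count)
  }
  list(stack = stack, efficiency = eff, mask = mask)
}
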