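#' Estimate spectral bleed-through factors from single-fluorophore controls
#'
#' The four crosstalk factors are per-cell intensity ratios in cells
#' expressing only one fluorophore: `S1 = F_d / D_d` and `S3 = A_d / D_d`
#' from donor-only cells, `S2 = F_a / A_a` and `S4 = D_a / A_a` from
#' acceptor-only cells. Per-cell ratios are aggregated by the median, which
#' is robust to occasional aberrant cells in the control populations.
#'
#' @param donor_only,acceptor_only Data frames of background-corrected
#'   intensities with numeric columns `donor`, `fret`, `acceptor`, one row
#'   per cell (or pixel). Cells whose reference channel (donor for the
#'   donor-only control, acceptor for the acceptor-only control) is not
#'   positive are dropped.
#' @return An object of class `bleedthrough_factors`: a list with elements
#'   `s1` (donor into FRET channel), `s2` (acceptor into FRET channel), `s3`
#'   (donor into acceptor channel), `s4` (acceptor into donor channel).
#' @examples
#' d <- data.frame(donor = c(1000, 1200), fret = c(250, 300), acceptor = 0)
#' a <- data.frame(donor = 0, fret = c(100, 110), acceptor = c(1000, 1100))
#' bleedthrough_factors(d, a)
#' @export
bleedthrough_factors <- function(donor_only, acceptor_only) {
  donor_only <- check_intensity_cols(donor_only, "donor_only")
  acceptor_only <- check_intensity_cols(acceptor_only, "acceptor_only")
  d <- dplyr::filter(donor_only, .data$donor > 0)
  a <- dplyr::filter(acceptor_only, .data$acceptor > 0)
  if (nrow(d) == 0 || nrow(a) == 0) {
    stop("Control populations must contain cells with positive reference-channel signal.",
      call. = FALSE
    )
  }
  out <- list(
    s1 = stats::median(d$fret / d$donor),
    s2 = stats::median(a$fret / a$acceptor),
    s3 = stats::median(d$acceptor / d$donor),
    s4 = stats::median(a$donor / a$acceptor)
  )
  structure(out, class = "bleedthrough_factors")
}

#' @export
print.bleedthrough_factors <- function(x, ...) {
  cat("Spectral bleed-through factors\n")
  cat(sprintf("  S1 (donor -> FRET channel):    %.5f\n", x$s1))
  cat(sprintf("  S2 (acceptor -> FRET channel): %.5f\n", x$s2))
  cat(sprintf("  S3 (donor -> acceptor ch.):    %.5f\n", x$s3))
  cat(sprintf("  S4 (acceptor -> donor ch.):    %.5f\n", x$s4))
  invisible(x)
}

#' Correct donor and acceptor signals for mutual spectral bleed-through
#'
#' Inverts the two-channel crosstalk mixing:
#' `D_c = (D_da - S4 * A_da) / (1 - S3*S4)` and
#' `A_c = (A_da - S3 * D_da) / (1 - S3*S4)`.
#' When `S3 = S4 = 0` the corrected signals equal the raw ones and this step
#' is a no-op.
#'
#' @param cells Data frame with numeric columns `donor`, `fret`, `acceptor`.
#' @param bleed A [bleedthrough_factors] object (or list with `s1`..`s4`).
#' @return The input as a tibble with columns `D_c` and `A_c` appended.
#' @export
correct_signals <- function(cells, bleed) {
  cells <- check_intensity_cols(cells, "cells")
  if (bleed$s3 * bleed$s4 >= 1) {
    stop("Singular bleed-through correction: S3 * S4 must be < 1.", call. = FALSE)
  }
  det <- 1 - bleed$s3 * bleed$s4
  dplyr::mutate(
    cells,
    D_c = (.data$donor - bleed$s4 * .data$acceptor) / det,
    A_c = (.data$acceptor - bleed$s3 * .data$donor) / det
  )
}

#' Bleed-through-corrected FRET signal (FRETc)
#'
#' Subtracts the donor and acceptor bleed-through contributions from the raw
#' FRET-channel signal: `FRETc = F_da - S1 * D_c - S2 * A_c`. May be
#' negative for noisy non-interacting cells; negative values are preserved
#' so population statistics remain unbiased.
#'
#' @param f_da Raw FRET-channel signal.
#' @param d_c,a_c Bleed-through-corrected donor and acceptor signals.
#' @param bleed A [bleedthrough_factors] object.
#' @return Numeric vector of corrected FRET signals.
#' @export
fret_c <- function(f_da, d_c, a_c, bleed) {
  f_da - d_c * bleed$s1 - a_c * bleed$s2
}

#' Gordon's normalized FRET measure (FRETN)
#'
#' `FRETN = FRETc / (G * D_c * A_c)`. The result carries reciprocal
#' intensity-squared units and is kept as such; it is provided for
#' comparison with the calibrated apparent efficiency, not as an efficiency
#' itself.
#'
#' @param fretc Corrected FRET signal.
#' @param d_c,a_c Corrected donor and acceptor signals (> 0).
#' @param g Instrument normalization factor G (also called alpha); > 0.
#' @return Numeric vector.
#' @export
fretn <- function(fretc, d_c, a_c, g = 1) {
  if (any(g <= 0)) stop("`g` must be positive.", call. = FALSE)
  if (any(d_c == 0 | a_c == 0, na.rm = TRUE)) {
    stop("FRETN is undefined for zero donor or acceptor signal.", call. = FALSE)
  }
  fretc / (g * d_c * a_c)
}

#' Xia's normalized FRET measure (N_FRET)
#'
#' `N_FRET = FRETc / sqrt(D_c * A_c)`. Dimensionless and scale-invariant,
#' but not an efficiency: on saturation series it peaks at intermediate
#' acceptor-to-donor ratios and declines again at high acceptor excess.
#'
#' @inheritParams fretn
#' @return Numeric vector.
#' @export
n_fret <- function(fretc, d_c, a_c) {
  if (any(d_c == 0 | a_c == 0, na.rm = TRUE)) {
    stop("N_FRET is undefined for zero donor or acceptor signal.", call. = FALSE)
  }
  fretc / sqrt(d_c * a_c)
}

#' Calibrated apparent FRET efficiency (DFRET)
#'
#' `DFRET = FRETc / (C1 * D_c + FRETc)`. With `C1` calibrated against a
#' construct of known transfer efficiency, the denominator is the total
#' donor-derived signal in FRET-channel-equivalent units, so DFRET equals
#' the apparent FRET efficiency of the cell.
#'
#' @param fretc Corrected FRET signal.
#' @param d_c Corrected donor signal.
#' @param c1 Donor-channel calibration factor (> 0).
#' @return Numeric vector of apparent efficiencies.
#' @export
dfret <- function(fretc, d_c, c1) {
  if (any(c1 <= 0)) stop("`c1` must be positive.", call. = FALSE)
  denom <- c1 * d_c + fretc
  if (any(denom == 0, na.rm = TRUE)) {
    stop("DFRET is undefined where C1 * D_c + FRETc is zero.", call. = FALSE)
  }
  fretc / denom
}

#' Derive the C1 and C2 calibration factors from a tandem-construct population
#'
#' A covalent donor-acceptor fusion ("tandem") has fixed 1:1 stoichiometry
#' and a transfer efficiency `e_ref` measurable independently by acceptor
#' photobleaching. Per cell,
#' `C1 = (F_c - e_ref * F_c) / (e_ref * D_c)` converts donor-channel into
#' FRET-channel-equivalent units, and `C2 = (D_c * C1 + F_c) / A_c` does the
#' same for the acceptor channel using the known 1:1 ratio. Per-cell values
#' are aggregated by the median.
#'
#' @param tandem Data frame with numeric columns `D_c`, `F_c`, `A_c`
#'   (bleed-through-corrected signals of the tandem population). Cells with
#'   any non-positive signal are dropped from the estimate.
#' @param e_ref Reference apparent FRET efficiency of the tandem construct,
#'   in (0, 1).
#' @param g Instrument factor stored for FRETN computation; default 1.
#' @return An object of class `calibration_factors`: list with `c1`, `c2`,
#'   `e_ref`, `g`, and `n_cells` used.
#' @export
calibration_factors <- function(tandem, e_ref, g = 1) {
  if (!is.numeric(e_ref) || length(e_ref) != 1 || e_ref <= 0 || e_ref >= 1) {
    stop("`e_ref` must be a single efficiency in (0, 1).", call. = FALSE)
  }
  need <- c("D_c", "F_c", "A_c")
  if (!all(need %in% names(tandem))) {
    stop("`tandem` must have columns D_c, F_c, A_c.", call. = FALSE)
  }
  ok <- dplyr::filter(
    tibble::as_tibble(tandem),
    .data$D_c > 0, .data$F_c > 0, .data$A_c > 0
  )
  if (nrow(ok) == 0) {
    stop("No tandem cells with positive corrected signals.", call. = FALSE)
  }
  c1_cell <- (ok$F_c - e_ref * ok$F_c) / (e_ref * ok$D_c)
  c1 <- stats::median(c1_cell)
  c2 <- stats::median((ok$D_c * c1 + ok$F_c) / ok$A_c)
  structure(
    list(c1 = c1, c2 = c2, e_ref = e_ref, g = g, n_cells = nrow(ok)),
    class = "calibration_factors"
  )
}

#' @export
print.calibration_factors <- function(x, ...) {
  cat("FRET calibration factors (tandem construct, E_ref =", x$e_ref, ")\n")
  cat(sprintf("  C1 (donor -> FRET units):    %.5f\n", x$c1))
  cat(sprintf("  C2 (acceptor -> FRET units): %.5f\n", x$c2))
  cat(sprintf("  cells used: %d;  G = %g\n", x$n_cells, x$g))
  invisible(x)
}

#' Molar acceptor-to-donor ratio from calibrated signals
#'
#' Evaluates `(D_c * C1 + F_c) / (A_c * C2)`, the ratio of the donor-derived
#' to the acceptor-derived abundance in FRET-channel-equivalent units. For a
#' tandem population this is 1 by construction of C2. Note the orientation:
#' the numerator is the donor-derived abundance, so the value is the
#' donor:acceptor ratio; the `ratio` column produced by [normalize_cells()]
#' is its reciprocal (acceptor:donor), the axis on which saturation curves
#' are plotted and fitting windows are defined.
#'
#' @param d_c,f_c,a_c Corrected donor, FRET, acceptor signals.
#' @param c1,c2 Calibration factors (> 0).
#' @return Numeric vector.
#' @export
molar_ratio <- function(d_c, f_c, a_c, c1, c2) {
  if (any(c2 <= 0)) stop("`c2` must be positive.", call. = FALSE)
  if (any(a_c == 0, na.rm = TRUE)) {
    stop("Molar ratio undefined for zero acceptor signal.", call. = FALSE)
  }
  (d_c * c1 + f_c) / (a_c * c2)
}

#' Full calibration from control populations
#'
#' Convenience wrapper running the complete calibration workflow: estimate
#' S1-S4 from single-fluorophore controls, correct the tandem population,
#' compute its FRETc, and derive C1/C2 against the reference efficiency.
#'
#' @inheritParams bleedthrough_factors
#' @param tandem Data frame of raw tandem-construct intensities with columns
#'   `donor`, `fret`, `acceptor`.
#' @param e_ref Reference efficiency of the tandem construct, in (0, 1).
#' @param g Instrument factor for FRETN; default 1.
#' @return A list of class `fret_calibration` with elements `bleed`
#'   ([bleedthrough_factors]) and `cal` ([calibration_factors]).
#' @export
calibrate <- function(donor_only, acceptor_only, tandem, e_ref, g = 1) {
  bleed <- bleedthrough_factors(donor_only, acceptor_only)
  td <- correct_signals(tandem, bleed)
  td$F_c <- fret_c(td$fret, td$D_c, td$A_c, bleed)
  cal <- calibration_factors(td, e_ref = e_ref, g = g)
  structure(list(bleed = bleed, cal = cal), class = "fret_calibration")
}

#' @export
print.fret_calibration <- function(x, ...) {
  print(x$bleed)
  print(x$cal)
  invisible(x)
}

#' Compute all FRET measures for a population of cells
#'
#' Applies the full normalization chain to a table of background-corrected
#' three-channel intensities: bleed-through correction, FRETc, FRETN,
#' N_FRET, the calibrated apparent efficiency DFRET, the donor- and
#' acceptor-derived abundances in FRET-channel-equivalent units, and the
#' acceptor-to-donor molar ratio.
#'
#' @param cells Data frame with numeric columns `donor`, `fret`, `acceptor`,
#'   one row per cell or pixel. Additional columns are passed through.
#' @param calibration A `fret_calibration` object from [calibrate()], or a
#'   list with elements `bleed` and `cal`.
#' @return A tibble: the input columns plus `D_c`, `A_c`, `FRETc`, `FRETN`,
#'   `N_FRET`, `DFRET`, `don`, `acc` (derived abundances) and `ratio`
#'   (acceptor:donor molar ratio). Measures whose denominator is not
#'   positive for a cell are `NA` for that cell rather than an error, so a
#'   gated population with a few degenerate cells normalizes cleanly.
#' @export
normalize_cells <- function(cells, calibration) {
  bleed <- calibration$bleed
  cal <- calibration$cal
  out <- correct_signals(cells, bleed)
  out <- dplyr::mutate(
    out,
    FRETc = fret_c(.data$fret, .data$D_c, .data$A_c, bleed),
    FRETN = dplyr::if_else(
      .data$D_c > 0 & .data$A_c > 0,
      .data$FRETc / (cal$g * .data$D_c * .data$A_c),
      NA_real_
    ),
    N_FRET = dplyr::if_else(
      .data$D_c > 0 & .data$A_c > 0,
      .data$FRETc / sqrt(.data$D_c * .data$A_c),
      NA_real_
    ),
    don = .data$D_c * cal$c1 + .data$FRETc,
    acc = .data$A_c * cal$c2,
    DFRET = dplyr::if_else(.data$don != 0, .data$FRETc / .data$don, NA_real_),
    ratio = dplyr::if_else(.data$don > 0, .data$acc / .data$don, NA_real_)
  )
  out
}

#' Gate out low-signal cells before calibration or fitting
#'
#' Excludes cells whose corrected donor or acceptor signal falls below an
#' inclusion floor. A practical floor is about three times the robust SD of
#' the corresponding channel's background in a single-color control, which
#' removes cells whose FRET measures are dominated by background noise.
#'
#' @param cells Data frame with columns `D_c` and `A_c` (e.g. from
#'   [normalize_cells()]).
#' @param floor Inclusion floor applied to both `D_c` and `A_c` (>= 0).
#' @return The filtered tibble.
#' @export
gate_cells <- function(cells, floor = 0) {
  if (!all(c("D_c", "A_c") %in% names(cells))) {
    stop("`cells` must have columns D_c and A_c.", call. = FALSE)
  }
  dplyr::filter(
    tibble::as_tibble(cells),
    .data$D_c > floor, .data$A_c > floor
  )
}

#' Moving-average DFRET saturation curve
#'
#' Orders cells by acceptor-to-donor ratio and computes a centered moving
#' average of both ratio and DFRET, producing the smooth red saturation
#' curve drawn over per-cell scatter plots. The curve is descriptive only;
#' model fitting always uses the raw per-cell values.
#'
#' @param cells Data frame with numeric columns `ratio` and `DFRET`, e.g.
#'   from [normalize_cells()]. Rows with `NA` in either are dropped.
#' @param window Odd-ish window width in cells (>= 1); `window = 1` returns
#'   the sorted raw points.
#' @return A tibble with columns `ratio`, `DFRET` (window means).
#' @export
aggregate_curve <- function(cells, window = 25) {
  if (!all(c("ratio", "DFRET") %in% names(cells))) {
    stop("`cells` must have columns ratio and DFRET.", call. = FALSE)
  }
  ok <- dplyr::filter(
    tibble::as_tibble(cells),
    is.finite(.data$ratio), is.finite(.data$DFRET)
  )
  ok <- dplyr::arrange(ok, .data$ratio)
  n <- nrow(ok)
  if (n < 2) {
    return(tibble::tibble(ratio = numeric(0), DFRET = numeric(0)))
  }
  window <- max(1L, as.integer(window))
  if (window == 1L) {
    return(dplyr::select(ok, "ratio", "DFRET"))
  }
  half <- (window - 1L) %/% 2L
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + half)
  tibble::tibble(
    ratio = purrr::map2_dbl(lo, hi, ~ mean(ok$ratio[.x:.y])),
    DFRET = purrr::map2_dbl(lo, hi, ~ mean(ok$DFRET[.x:.y]))
  )
}

check_intensity_cols <- function(x, name) {
  need <- c("donor", "fret", "acceptor")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("`", name, "` must be a data frame with columns donor, fret, acceptor.",
      call. = FALSE
    )
  }
  tibble::as_tibble(x)
}
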