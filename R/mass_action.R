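#' Equilibrium complex concentration under the law of mass action
#'
#' Solves the bimolecular binding equilibrium `don + acc <-> complex` for the
#' complex concentration at equilibrium, given total donor and acceptor
#' concentrations, the association constant `ka`, and a stoichiometry factor
#' `z` giving the number of acceptor molecules per donor molecule within the
#' complex (so the acceptor pool available for complex formation is `acc / z`
#' in donor-equivalent units). Concentrations may be molar (e.g. nM with `ka`
#' in 1/nM) or fluorescence-intensity units with `ka` an apparent affinity in
#' reciprocal intensity units; the algebra is identical.
#'
#' The equilibrium is the root of the quadratic
#' `ka * c^2 - (ka*don + ka*acc/z + 1) * c + ka * don * acc/z = 0`
#' lying in `[0, min(don, acc/z)]`. The root is evaluated in its conjugate
#' (rationalized) form, `2 * ka * don * (acc/z) / (s + sqrt(s^2 - 4 * ka^2 *
#' don * acc/z))` with `s = ka*don + ka*acc/z + 1`, which stays fully
#' accurate for very large `ka` where the textbook `(s - sqrt(...)) / (2*ka)`
#' form loses all significant digits to cancellation.
#'
#' @param don Numeric vector of total donor concentrations (>= 0).
#' @param acc Numeric vector of total acceptor concentrations (>= 0).
#' @param ka Association constant(s), > 0, in reciprocal concentration units.
#' @param z Stoichiometry factor(s): acceptor molecules per donor molecule in
#'   the complex (> 0). `z = 0.5` describes a trimer with two donor-tagged
#'   molecules per acceptor-tagged molecule.
#'
#' @return A tibble with columns `don`, `acc`, `complex`, `don_free`,
#'   `acc_free`. Mass conservation holds exactly: `don_free = don - complex`
#'   and `acc_free = acc - z * complex`.
#'
#' @examples
#' complex_concentration(don = 1, acc = 1, ka = 1)
#' # saturation: effectively infinite affinity, acceptor in excess
#' complex_concentration(don = 1, acc = 5, ka = 1e12)
#' @export
complex_concentration <- function(don, acc, ka, z = 1) {
  stop_if_bad_concentration(don, "don")
  stop_if_bad_concentration(acc, "acc")
  stop_if_bad_parameter(ka, "ka")
  stop_if_bad_parameter(z, "z")
  n <- max(length(don), length(acc), length(ka), length(z))
  don <- rep_len(don, n)
  acc <- rep_len(acc, n)
  ka <- rep_len(ka, n)
  z <- rep_len(z, n)

  cplx <- mass_action_root(don, acc / z, ka)
  tibble::tibble(
    don = don,
    acc = acc,
    complex = cplx,
    don_free = don - cplx,
    acc_free = acc - z * cplx
  )
}

# Stable root of ka*c^2 - (ka*a + ka*b + 1)*c + ka*a*b = 0 on [0, min(a, b)].
# a, b are the two reactant totals in donor-equivalent units.
mass_action_root <- function(a, b, ka) {
  s <- ka * a + ka * b + 1
  disc <- s^2 - 4 * ka^2 * a * b
  # disc = (ka*(a-b))^2 + 2*ka*(a+b) + 1 > 0 always; clamp roundoff
  disc[disc < 0] <- 0
  2 * ka * a * b / (s + sqrt(disc))
}

#' Apparent FRET efficiency of a population
#'
#' The apparent (population-averaged) FRET efficiency is the maximal transfer
#' efficiency of the bound pair scaled by the fraction of donor molecules
#' engaged in a complex: `fret_max * complex / don`.
#'
#' @param complex Complex concentration(s) (>= 0).
#' @param don Total donor concentration(s) (> 0).
#' @param fret_max Maximal FRET efficiency at complete donor saturation, in
#'   `[0, 1]`.
#' @return Numeric vector of apparent efficiencies in `[0, fret_max]`.
#' @examples
#' apparent_efficiency(complex = 0.5, don = 1, fret_max = 0.35)
#' @export
apparent_efficiency <- function(complex, don, fret_max) {
  if (any(!is.finite(don)) || any(don <= 0)) {
    stop("`don` must be positive and finite: apparent efficiency is a per-donor ratio.",
      call. = FALSE
    )
  }
  if (any(fret_max < 0) || any(fret_max > 1)) {
    stop("`fret_max` must lie in [0, 1].", call. = FALSE)
  }
  fret_max * complex / don
}

#' Synthesize three-channel FRET intensities from an equilibrium state
#'
#' Computes the theoretical background-corrected donor-channel, acceptor-
#' channel and raw FRET-channel signals of a population with given free and
#' bound species, maximal transfer efficiency, and spectral bleed-through
#' factors. Donor fluorescence is quenched by FRET within the complex
#' (`complex * (1 - fret_max)`), the acceptor fluorescence of the complex is
#' `z * complex` (one acceptor per complex at the default `z = 1`), and the
#' raw FRET channel carries the sensitized emission `complex * fret_max` plus
#' bleed-through from the (already mixed) donor and acceptor channel signals:
#'
#' \preformatted{
#'   D_da = don_free + complex*(1 - fret_max) + (acc_free + z*complex)*S4
#'   A_da = acc_free + z*complex + (don_free + complex*(1 - fret_max))*S3
#'   F_da = complex*fret_max + S1*D_da + S2*A_da
#' }
#'
#' Note that `F_da` applies `S1`/`S2` to the bleed-contaminated `D_da` and
#' `A_da` rather than to the pure fluorophore signals, so with all four
#' factors nonzero a small second-order cross term enters the FRET channel;
#' this matches the defining equations of the measurement model and is kept
#' as such (see the methods vignette).
#'
#' @param don_free,acc_free,complex Species concentrations (vectors recycle).
#' @param fret_max Maximal FRET efficiency in `[0, 1]`.
#' @param s1 Donor bleed-through into the FRET channel (>= 0).
#' @param s2 Acceptor bleed-through into the FRET channel (>= 0).
#' @param s3 Donor bleed-through into the acceptor channel (>= 0).
#' @param s4 Acceptor bleed-through into the donor channel (>= 0).
#' @param z Stoichiometry factor (acceptors per donor in the complex).
#' @return A tibble with columns `D_da`, `F_da`, `A_da`.
#' @examples
#' simulate_channels(don_free = 0, acc_free = 0, complex = 1, fret_max = 0.35)
#' @export
simulate_channels <- function(don_free, acc_free, complex, fret_max,
                              s1 = 0, s2 = 0, s3 = 0, s4 = 0, z = 1) {
  if (any(c(s1, s2, s3, s4) < 0)) {
    stop("Bleed-through factors must be non-negative.", call. = FALSE)
  }
  d_pure <- don_free + complex * (1 - fret_max)
  a_pure <- acc_free + z * complex
  d_da <- d_pure + a_pure * s4
  a_da <- a_pure + d_pure * s3
  f_da <- complex * fret_max + s1 * d_da + s2 * a_da
  tibble::tibble(D_da = d_da, F_da = f_da, A_da = a_da)
}

#' Saturation curve of apparent FRET efficiency versus acceptor excess
#'
#' Evaluates the mass-action model over a grid of total acceptor
#' concentrations at fixed total donor, returning the apparent FRET
#' efficiency as a function of the acceptor-to-donor ratio. This is the
#' theoretical saturation curve: monotone non-decreasing in acceptor excess,
#' with plateau `fret_max`.
#'
#' @param don Total donor concentration (single positive value).
#' @param acc_grid Numeric vector of total acceptor concentrations (>= 0).
#' @param ka Association constant (> 0).
#' @param fret_max Maximal FRET efficiency in `[0, 1]`.
#' @param z Stoichiometry factor.
#' @return A tibble with columns `acc`, `don`, `ratio` (= acc/don),
#'   `complex`, `efficiency`.
#' @examples
#' saturation_curve(don = 100, acc_grid = 10^seq(0, 4.6, length.out = 25),
#'                  ka = 1, fret_max = 0.35)
#' @export
saturation_curve <- function(don, acc_grid, ka, fret_max, z = 1) {
  if (length(don) != 1 || !is.finite(don) || don <= 0) {
    stop("`don` must be a single positive concentration.", call. = FALSE)
  }
  if (length(acc_grid) == 0) {
    stop("`acc_grid` must be non-empty.", call. = FALSE)
  }
  st <- complex_concentration(don = don, acc = acc_grid, ka = ka, z = z)
  tibble::tibble(
    acc = st$acc,
    don = st$don,
    ratio = st$acc / st$don,
    complex = st$complex,
    efficiency = apparent_efficiency(st$complex, st$don, fret_max)
  )
}

stop_if_bad_concentration <- function(x, name) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x < 0)) {
    stop("`", name, "` must be finite and non-negative.", call. = FALSE)
  }
  invisible(x)
}

stop_if_bad_parameter <- function(x, name) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be finite and strictly positive.", call. = FALSE)
  }
  invisible(x)
}
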