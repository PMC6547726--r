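#' Estimate donor and acceptor bleaching artifact factors from controls
#'
#' Acceptor photobleaching measures FRET as donor de-quenching, but strong
#' acceptor-wavelength illumination can itself change the donor-channel
#' signal: donors may co-bleach or photoactivate (factor `df`), and bleached
#' acceptors may photoswitch into an emission profile detected in the donor
#' channel (factor `af`). Both are estimated from control samples containing
#' only one fluorophore:
#' `df = (D_dpost - D_dpre) / D_dpre` per donor-only record and
#' `af = (D_apost - D_apre) / (A_apre - A_apost)` per acceptor-only record,
#' aggregated by the median. The factors are experiment-level: estimated
#' once per imaging session and applied to every bleached ROI of that
#' session.
#'
#' @param donor_only Data frame with numeric columns `D_pre`, `D_post`:
#'   donor-channel signal of donor-only cells before/after the bleach pulse.
#' @param acceptor_only Data frame with numeric columns `D_pre`, `D_post`,
#'   `A_pre`, `A_post` for acceptor-only cells.
#' @return An object of class `bleach_controls`: list with `df` (signed; can
#'   be negative for co-bleaching, positive for photoactivation) and `af`.
#' @examples
#' d <- data.frame(D_pre = 1000, D_post = 950)
#' a <- data.frame(D_pre = 100, D_post = 120, A_pre = 1000, A_post = 200)
#' bleach_controls(d, a)
#' @export
bleach_controls <- function(donor_only, acceptor_only) {
  if (!all(c("D_pre", "D_post") %in% names(donor_only))) {
    stop("`donor_only` needs columns D_pre, D_post.", call. = FALSE)
  }
  if (!all(c("D_pre", "D_post", "A_pre", "A_post") %in% names(acceptor_only))) {
    stop("`acceptor_only` needs columns D_pre, D_post, A_pre, A_post.",
      call. = FALSE
    )
  }
  if (any(donor_only$D_pre <= 0)) {
    stop("Donor-only controls require positive pre-bleach donor signal.",
      call. = FALSE
    )
  }
  dA <- acceptor_only$A_pre - acceptor_only$A_post
  if (any(dA == 0)) {
    stop("Acceptor-only controls show no acceptor-signal decrease; af is undefined.",
      call. = FALSE
    )
  }
  structure(
    list(
      df = stats::median((donor_only$D_post - donor_only$D_pre) / donor_only$D_pre),
      af = stats::median((acceptor_only$D_post - acceptor_only$D_pre) / dA)
    ),
    class = "bleach_controls"
  )
}

#' @export
print.bleach_controls <- function(x, ...) {
  cat("Acceptor-bleaching artifact factors\n")
  cat(sprintf("  df (donor co-bleach/photoactivation): %+.5f\n", x$df))
  cat(sprintf("  af (acceptor photoswitching):         %+.5f\n", x$af))
  invisible(x)
}

#' FRET efficiency from acceptor photobleaching
#'
#' Computes the apparent FRET efficiency from pre/post acceptor-bleach
#' intensity pairs, correcting the donor-channel increase for donor
#' co-bleaching/photoactivation (`df`), acceptor photoswitching (`af`) and
#' incomplete acceptor bleaching. The artifact- and completeness-corrected
#' donor gain is
#'
#' \preformatted{
#'   dD = ((D_post - df*D_pre - af*(A_pre - A_post)) - D_pre) /
#'        (1 - A_post / A_pre)
#' }
#'
#' and the efficiency `E = dD / (D_pre + dD)`, the fraction of the
#' unquenched donor emission that had been lost to FRET. The denominator
#' `1 - A_post/A_pre` rescales a partial bleach to the full-bleach donor
#' gain, so `E` is independent of bleach completeness.
#'
#' @param records Data frame with numeric columns `D_pre`, `D_post`,
#'   `A_pre`, `A_post`, one row per bleached cell or ROI.
#' @param controls A [bleach_controls] object (or list with `df`, `af`).
#'   Defaults to no artifacts.
#' @return The input as a tibble with columns `delta_D` (corrected donor
#'   gain) and `E` (apparent FRET efficiency) appended.
#' @examples
#' rec <- data.frame(D_pre = 70, D_post = 100, A_pre = 1000, A_post = 0)
#' bleach_efficiency(rec)
#' @export
bleach_efficiency <- function(records, controls = list(df = 0, af = 0)) {
  need <- c("D_pre", "D_post", "A_pre", "A_post")
  if (!all(need %in% names(records))) {
    stop("`records` needs columns D_pre, D_post, A_pre, A_post.", call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  if (any(records$A_pre <= 0)) {
    stop("Pre-bleach acceptor signal must be positive.", call. = FALSE)
  }
  frac <- 1 - records$A_post / records$A_pre
  if (any(frac <= 0)) {
    stop(
      "No acceptor-signal decrease in ", sum(frac <= 0),
      " record(s): bleaching efficiency cannot be computed.",
      call. = FALSE
    )
  }
  dD <- ((records$D_post - controls$df * records$D_pre -
    controls$af * (records$A_pre - records$A_post)) - records$D_pre) / frac
  dplyr::mutate(records, delta_D = dD, E = dD / (.data$D_pre + dD))
}
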