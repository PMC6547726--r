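#' Donor- and acceptor-derived abundances in FRET-channel-equivalent units
#'
#' Converts calibrated per-cell signals into the relative abundances used by
#' the saturation-curve fit: `don = D_c * C1 + F_c` (total donor-derived
#' signal, including the part re-emitted through FRET) and
#' `acc = A_c * C2`. Both are proportional to the underlying molecular
#' concentrations with a shared unknown instrument factor.
#'
#' @param d_c,f_c,a_c Corrected donor, FRET, acceptor signals.
#' @param c1,c2 Calibration factors from [calibration_factors()].
#' @return A tibble with columns `don` and `acc`.
#' @export
derived_abundances <- function(d_c, f_c, a_c, c1, c2) {
  tibble::tibble(don = d_c * c1 + f_c, acc = a_c * c2)
}

#' Predicted DFRET under the mass-action binding model
#'
#' The model value of the apparent FRET efficiency for a cell with derived
#' abundances `don` and `acc`: the mass-action complex concentration (with
#' apparent affinity `ka` in reciprocal-intensity units and stoichiometry
#' `z`) times `fret_max / don`. Shares the numerically stable quadratic-root
#' implementation of [complex_concentration()], so it is usable at
#' effectively infinite affinities.
#'
#' @param don,acc Derived abundances (don > 0, acc >= 0); vectors recycle.
#' @param ka Apparent association constant (> 0, reciprocal intensity units).
#' @param z Stoichiometry factor (> 0).
#' @param fret_max Maximal FRET efficiency in `[0, 1]`.
#' @return Numeric vector of predicted DFRET values.
#' @examples
#' predict_dfret(don = 1, acc = 1, ka = 1, z = 1, fret_max = 0.35)
#' @export
predict_dfret <- function(don, acc, ka, z = 1, fret_max) {
  stop_if_bad_parameter(ka, "ka")
  stop_if_bad_parameter(z, "z")
  if (any(don <= 0)) stop("`don` must be positive.", call. = FALSE)
  fret_max * mass_action_root(don, acc / z, ka) / don
}

#' Fit the mass-action model to a per-cell DFRET population
#'
#' Estimates the apparent affinity constant `Ka_app`, the complex
#' stoichiometry `z` and the saturation efficiency `FRET_max` by nonlinear
#' least squares, minimizing the squared deviation between observed per-cell
#' DFRET values and the mass-action prediction from each cell's derived
#' donor and acceptor abundances. The fit is restricted to cells whose
#' acceptor-to-donor ratio lies inside `window`; for a 1:1 interaction the
#' default window `[0.2, 2]` brackets the stoichiometric point, and for a
#' suspected non-1:1 complex the window should be shifted/scaled around the
#' expected ratio (e.g. `[0.1, 1]` for a 2-donor:1-acceptor trimer).
#'
#' Internally the affinity is parameterized as `log10(Ka_app)` for
#' conditioning (apparent affinities span many orders of magnitude);
#' estimates and standard errors are reported on the natural scale via the
#' delta method. Optimization uses Levenberg-Marquardt with box bounds.
#' Standard errors come from the estimated parameter covariance at the
#' optimum; `t = estimate / SE` and two-sided p values use a t distribution
#' with `n_used - 3` degrees of freedom.
#'
#' @param cells Data frame with numeric columns `don`, `acc` and `DFRET`
#'   (per-cell observations, e.g. from [normalize_cells()]); rows with
#'   non-positive `don`/`acc` or non-finite DFRET are dropped.
#' @param window Length-2 numeric, inclusive acceptor:donor ratio window.
#' @param init Optional named list overriding starting values: any of `ka`,
#'   `z`, `fret_max`. Defaults: `z = 1`, `fret_max` = 95th percentile of
#'   in-window DFRET, `ka = 1 / median(don)`.
#' @param bounds Named list of length-2 ranges for `log10_ka`, `z`,
#'   `fret_max`.
#' @param min_cells Minimum number of in-window cells required.
#' @return An object of class `fret_fit`; see [tidy.fret_fit()] and
#'   [glance.fret_fit()]. Key elements: `coefficients` (tibble with
#'   estimate, std.error, statistic, p.value per parameter), `n_used`,
#'   `window`, `fitted`, `residuals`, `converged`.
#' @export
fit_interaction <- function(cells,
                            window = c(0.2, 2),
                            init = list(),
                            bounds = list(
                              log10_ka = c(-12, 12),
                              z = c(0.05, 20),
                              fret_max = c(1e-6, 1)
                            ),
                            min_cells = 10) {
  cells <- tibble::as_tibble(cells)
  dfret_col <- intersect(c("DFRET", "dfret"), names(cells))[1]
  if (!all(c("don", "acc") %in% names(cells)) || is.na(dfret_col)) {
    stop("`cells` must have columns don, acc and DFRET.", call. = FALSE)
  }
  obs <- tibble::tibble(
    don = cells$don, acc = cells$acc, DFRET = cells[[dfret_col]]
  )
  obs <- dplyr::filter(
    obs,
    is.finite(.data$don), is.finite(.data$acc), is.finite(.data$DFRET),
    .data$don > 0, .data$acc > 0
  )
  obs$ratio <- obs$acc / obs$don
  inwin <- dplyr::filter(
    obs, .data$ratio >= window[1], .data$ratio <= window[2]
  )
  if (nrow(inwin) < max(min_cells, 4)) {
    stop(
      "Only ", nrow(inwin), " cells inside the ratio window [",
      window[1], ", ", window[2], "]; at least ", max(min_cells, 4),
      " required.",
      call. = FALSE
    )
  }

  start <- list(
    lka = log10(if (!is.null(init$ka)) init$ka else 1 / stats::median(inwin$don)),
    z = if (!is.null(init$z)) init$z else 1,
    fmax = if (!is.null(init$fret_max)) {
      init$fret_max
    } else {
      max(min(stats::quantile(inwin$DFRET, 0.95, names = FALSE), 0.99), 0.01)
    }
  )
  lower <- c(bounds$log10_ka[1], bounds$z[1], bounds$fret_max[1])
  upper <- c(bounds$log10_ka[2], bounds$z[2], bounds$fret_max[2])
  start$lka <- min(max(start$lka, lower[1]), upper[1])
  start$z <- min(max(start$z, lower[2]), upper[2])

  fit <- tryCatch(
    minpack.lm::nlsLM(
      DFRET ~ predict_dfret(don, acc, ka = 10^lka, z = z, fret_max = fmax),
      data = inwin,
      start = start,
      lower = lower,
      upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = 1e-10, ptol = 1e-8
      )
    ),
    error = function(e) {
      stop("Nonlinear fit failed: ", conditionMessage(e), call. = FALSE)
    }
  )

  sm <- summary(fit)
  co <- sm$coefficients
  n_used <- nrow(inwin)
  dof <- n_used - 3L

  lka_hat <- co["lka", "Estimate"]
  lka_se <- co["lka", "Std. Error"]
  ka_hat <- 10^lka_hat
  ka_se <- log(10) * ka_hat * lka_se # delta method

  est <- c(ka_hat, co["z", "Estimate"], co["fmax", "Estimate"])
  se <- c(ka_se, co["z", "Std. Error"], co["fmax", "Std. Error"])
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = dof)

  coefficients <- tibble::tibble(
    term = c("Ka_app", "z", "FRET_max"),
    estimate = est,
    std.error = se,
    statistic = tval,
    p.value = pval
  )

  res <- stats::residuals(fit)
  structure(
    list(
      coefficients = coefficients,
      log10_ka = c(estimate = lka_hat, std.error = lka_se),
      n_used = n_used,
      df.residual = dof,
      window = window,
      sigma = sm$sigma,
      sse = sum(res^2),
      converged = fit$convInfo$isConv,
      iterations = fit$convInfo$finIter,
      data = inwin,
      fitted = as.numeric(stats::fitted(fit)),
      residuals = as.numeric(res),
      nls = fit
    ),
    class = "fret_fit"
  )
}

#' @export
print.fret_fit <- function(x, digits = 4, ...) {
  cat("Mass-action fit of the DFRET saturation data\n")
  cat(sprintf(
    "  %d cells in acceptor:donor ratio window [%g, %g]\n",
    x$n_used, x$window[1], x$window[2]
  ))
  co <- as.data.frame(x$coefficients)
  rownames(co) <- co$term
  co$term <- NULL
  names(co) <- c("Estimate", "Std. Error", "t value", "Pr(>|t|)")
  stats::printCoefmat(as.matrix(co), digits = digits, P.values = TRUE,
    has.Pvalue = TRUE)
  cat(sprintf(
    "  residual std. error %.4g on %d degrees of freedom (%s, %d iterations)\n",
    x$sigma, x$df.residual,
    if (isTRUE(x$converged)) "converged" else "NOT converged",
    x$iterations
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy the parameter table of a mass-action DFRET fit
#'
#' @param x A `fret_fit` object from [fit_interaction()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`Ka_app`, `z`, `FRET_max`)
#'   and columns `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.fret_fit <- function(x, ...) {
  x$coefficients
}

#' One-row fit summary of a mass-action DFRET fit
#'
#' @param x A `fret_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `n_used`, `df.residual`, `sigma`,
#'   `deviance` (residual sum of squares), `converged`, `iterations` and the
#'   window bounds.
#' @export
glance.fret_fit <- function(x, ...) {
  tibble::tibble(
    n_used = x$n_used,
    df.residual = x$df.residual,
    sigma = x$sigma,
    deviance = x$sse,
    converged = x$converged,
    iterations = x$iterations,
    window_low = x$window[1],
    window_high = x$window[2]
  )
}

#' Per-cell observations with fitted values and residuals
#'
#' @param x A `fret_fit` object.
#' @param ... Unused.
#' @return The in-window cell table with `.fitted` and `.resid` columns.
#' @export
augment.fret_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = x$residuals)
}

#' Extract fitted parameters as a named vector
#' @param object A `fret_fit` object.
#' @param ... Unused.
#' @export
coef.fret_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}
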