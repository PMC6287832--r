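#' Logistic dose-response curve on the log-concentration axis
#'
#' The steady-state activation of the two-stage receptor model, plotted
#' against `C = log10(c)`, is exactly a logistic (Hill) curve
#' `g(C) = gmax / (1 + exp(-nprime * (C - C_half)))` with plateau
#' `gmax = K2prime`, inflection `C_half` (the log10 concentration of
#' half-maximal activation) and slope `nprime = n * ln(10)`.
#'
#' @param C log10 concentration(s).
#' @param gmax plateau in (0, 1).
#' @param C_half inflection point (log10 concentration).
#' @param n Hill coefficient of the kinetic model; the logistic slope is
#'   `n * ln(10)`.
#' @return response values in (0, gmax).
#' @export
hill_response <- function(C, gmax, C_half, n) {
  gmax / (1 + exp(-n * log(10) * (C - C_half)))
}

#' Calibrate rate constants from Hill-curve descriptors
#'
#' Inverts the steady-state dose-response relation: given a combination's
#' plateau `gmax`, half-activation point `C_half` and Hill coefficient `n`,
#' together with the unbinding rate `k_minus1` and activation rate `k2` that
#' fix the kinetic timescale, returns a full set of rate constants whose
#' steady-state curve reproduces the Hill descriptors exactly:
#' `K2 = gmax / (1 - gmax)`, `k_minus2 = k2 / K2`, and
#' `k1 = (k_minus1 / (1 + K2))^(1/n) * 10^(-C_half)` so that the activated
#' fraction at `c = 10^C_half` equals `gmax / 2`. `k1` is clamped to the hard
#' interval (0.1, 5000) ms^-1 with a warning.
#'
#' @param gmax plateau(s) in (0, 1), interpreted as the maximal activated
#'   fraction `K2prime`.
#' @param C_half half-activation point(s), log10 concentration.
#' @param n Hill coefficient(s).
#' @param k_minus1 unbinding rate (ms^-1).
#' @param k2 activation rate (ms^-1).
#' @param odor_id,receptor_id optional identifiers.
#' @return tibble of rate constants (see [rate_constants()]).
#' @examples
#' p <- calibrate_from_hill(gmax = 1/3, C_half = -3, n = 0.65)
#' steady_state(p, 1e-3) # = gmax / 2
#' @export
calibrate_from_hill <- function(gmax, C_half, n, k_minus1 = 0.03, k2 = 0.1,
                                odor_id = NULL, receptor_id = NULL) {
  if (any(gmax <= 0 | gmax >= 1)) stop("gmax must lie in (0, 1)", call. = FALSE)
  m <- max(length(gmax), length(C_half), length(n))
  gmax <- rep_len(gmax, m); C_half <- rep_len(C_half, m); n <- rep_len(n, m)
  k_minus1 <- rep_len(k_minus1, m); k2 <- rep_len(k2, m)
  K2 <- gmax / (1 - gmax)
  k1 <- (k_minus1 / (1 + K2))^(1 / n) * 10^(-C_half)
  if (any(k1 < 0.1 | k1 > 5000)) {
    warning(sum(k1 < 0.1 | k1 > 5000),
            " calibrated k1 value(s) outside (0.1, 5000); clamped", call. = FALSE)
    k1 <- pmin(pmax(k1, 0.1), 5000)
  }
  rate_constants(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_minus2 = k2 / K2,
                 n = n, odor_id = odor_id, receptor_id = receptor_id)
}
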