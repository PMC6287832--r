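#' Integrate the receptor binding/activation dynamics
#'
#' Solves the full two-stage kinetics for a (possibly single-component)
#' mixture on one receptor. The state is the unbound fraction `r0` plus, per
#' component, the bound fraction `r_i` and activated fraction `rstar_i`; mass
#' is conserved (`r0 + sum(r_i + rstar_i) = 1`) and all receptors start
#' unbound. The consistent model depletes free receptors at
#' `(sum k1_j c_j)^n` and feeds component `i` at
#' `w(n) * (k1_i c_i)^n`; the legacy variant sets `w = 1` and depletes at
#' `sum (k1_j c_j)^n`, which is why it fails self-mixture consistency.
#'
#' Stiffness: rate constants in realistic ensembles span several orders of
#' magnitude, so the solver is `deSolve`'s stiff-capable `lsoda` at tight
#' tolerances (rtol 1e-8, atol 1e-10).
#'
#' @param params tibble of rate constants for the mixture components
#'   (shared `n`).
#' @param conc per-component concentrations: a numeric vector (constant
#'   stimulus), or a function `conc(t)` returning the concentration vector at
#'   time `t` (ms) for pulsed/time-varying stimuli.
#' @param times increasing time grid (ms) starting at stimulus onset.
#' @param model `"consistent"` (default) or `"legacy"`.
#' @param rtol,atol solver tolerances.
#' @return a tibble of class `"receptor_trajectory"` in tidy form with columns
#'   `time_ms`, `component`, `r0`, `r`, `rstar` plus attribute
#'   `rstar_total` evaluated on the grid.
#' @examples
#' p <- rate_constants(1.2, 0.03, 0.1, 0.2, 0.65)
#' tr <- integrate_kinetics(p, conc = 0.01, times = seq(0, 200, 1))
#' @export
integrate_kinetics <- function(params, conc, times,
                               model = c("consistent", "legacy"),
                               rtol = 1e-8, atol = 1e-10) {
  model <- match.arg(model)
  d <- derive_constants(params)
  if (length(unique(d$n)) != 1) {
    stop("mixture components must share the Hill coefficient n", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  n <- d$n[1]
  m <- nrow(d)
  conc_fun <- if (is.function(conc)) {
    conc
  } else {
    conc_vec <- rep_len(conc, m)
    function(t) conc_vec
  }

  deriv <- function(t, state, parms) {
    r0 <- state[1]
    r <- state[1 + seq_len(m)]
    rstar <- state[1 + m + seq_len(m)]
    ci <- rep_len(conc_fun(t), m)
    b <- d$k1 * ci
    bn <- b^n
    if (all(b == 0)) {
      deplete <- 0
      feed <- rep(0, m)
    } else if (model == "consistent") {
      deplete <- sum(b)^n
      w <- deplete / sum(bn)
      feed <- w * bn
    } else {
      deplete <- sum(bn)
      feed <- bn
    }
    dr0 <- sum(d$k_minus1 * r) - deplete * r0
    dr <- feed * r0 - d$k_minus1 * r + d$k_minus2 * rstar - d$k2 * r
    drstar <- d$k2 * r - d$k_minus2 * rstar
    list(c(dr0, dr, drstar))
  }

  y0 <- c(1, rep(0, 2 * m))
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("receptor ODE integration failed (istate = ", attr(sol, "istate")[1],
         "); consider a finer time grid or looser tolerances", call. = FALSE)
  }
  sol <- as.matrix(sol)
  comp_ids <- if (!is.null(params$odor_id)) params$odor_id else paste0("component", seq_len(m))
  out <- tibble::tibble(
    time_ms = rep(sol[, 1], m),
    component = rep(comp_ids, each = nrow(sol)),
    r0 = rep(sol[, 2], m),
    r = as.vector(sol[, 2 + seq_len(m), drop = FALSE]),
    rstar = as.vector(sol[, 2 + m + seq_len(m), drop = FALSE])
  )
  attr(out, "rstar_total") <- rowSums(sol[, 2 + m + seq_len(m), drop = FALSE])
  attr(out, "times") <- sol[, 1]
  attr(out, "model") <- model
  class(out) <- c("receptor_trajectory", class(out))
  out
}

#' Total activated fraction along a trajectory
#'
#' @param trajectory a `"receptor_trajectory"` from [integrate_kinetics()].
#' @return tibble with `time_ms` and `rstar_total`.
#' @export
trajectory_total <- function(trajectory) {
  tibble::tibble(
    time_ms = attr(trajectory, "times"),
    rstar_total = attr(trajectory, "rstar_total")
  )
}

#' Integrate to steady state
#'
#' Runs [integrate_kinetics()] on successive windows until the largest time
#' derivative of the state falls below `deriv_tol` (in 1/ms) or `t_max` is
#' reached; non-convergence is flagged with a warning.
#'
#' Near receptor saturation the redistribution of bound receptors between
#' competing components can be very slow (its timescale is roughly
#' `1 / (k_minus1 * r0)`, and `r0` is tiny at high concentration), so the
#' default 10^4 ms horizon may flag non-convergence for such draws; raise
#' `t_max` when the exact asymptote is required.
#'
#' @inheritParams integrate_kinetics
#' @param deriv_tol convergence threshold on `max |d state/dt|` (1/ms).
#' @param t_max time horizon (ms).
#' @return a one-row tibble like [steady_state_mixture()]'s, with an extra
#'   logical column `converged`.
#' @export
integrate_to_steady_state <- function(params, conc, model = c("consistent", "legacy"),
                                      deriv_tol = 1e-10, t_max = 1e4) {
  model <- match.arg(model)
  d <- derive_constants(params)
  m <- nrow(d)
  t_lo <- 0
  window <- 500
  state_cols <- function(tr) {
    tot <- trajectory_total(tr)
    last <- dplyr::filter(tr, .data$time_ms == max(.data$time_ms))
    list(r0 = last$r0[1], r = last$r, rstar = last$rstar,
         rstar_total = tot$rstar_total[nrow(tot)])
  }
  # derivative magnitude estimated by finite differences on a fine tail grid
  repeat {
    times <- seq(t_lo, min(t_lo + window, t_max), length.out = 201)
    if (t_lo == 0) {
      tr <- integrate_kinetics(params, conc, times, model = model)
    } else {
      tr <- integrate_kinetics(params, conc, c(0, times[-1]), model = model)
    }
    tot <- trajectory_total(tr)
    k <- nrow(tot)
    dt <- tot$time_ms[k] - tot$time_ms[k - 1]
    rate <- abs(tot$rstar_total[k] - tot$rstar_total[k - 1]) / dt
    if (rate < deriv_tol || times[length(times)] >= t_max) {
      st <- state_cols(tr)
      converged <- rate < deriv_tol
      if (!converged) {
        warning("steady state not reached by t = ", t_max, " ms", call. = FALSE)
      }
      return(tibble::tibble(
        rstar_total = st$rstar_total, r0 = st$r0,
        rstar = list(st$rstar), r = list(st$r), converged = converged
      ))
    }
    t_lo <- 0
    window <- window * 4
  }
}
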