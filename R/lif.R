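#' Leaky integrate-and-fire parameters
#'
#' Conductance-based LIF-with-adaptation parameters for one neuron population
#' of the antennal lobe model. Defaults are the published honey-bee
#' calibration: membrane time constant 20 ms, excitatory/inhibitory reversal
#' potentials 50/-75 mV, rest and reset -70 mV, threshold -50 mV, leak 1 nS,
#' refractory period 2 ms; the adaptation current decays with 60 ms (ORN) or
#' 25 ms (PN/LN) and its post-spike amplitude is `I_adapt_base` times the
#' driving input (total receptor activation for ORNs, presynaptic rate in
#' spikes/ms for PNs and LNs). Background conductances (nS, relative to the
#' leak) are nonzero for ORNs and PNs only.
#'
#' @param population `"ORN"`, `"PN"` or `"LN"`: selects published defaults.
#' @param tau_m,V_e,V_i,V_r,V_th,V_reset,g_l,t_refract,tau_adapt,I_adapt_base
#'   overrides of the population defaults (ms, mV, nS as appropriate).
#' @param background_ge,background_gi background conductances (nS).
#' @return object of class `"lif_params"` (a named list).
#' @examples
#' lif_params("ORN")
#' @export
lif_params <- function(population = c("ORN", "PN", "LN"),
                       tau_m = 20, V_e = 50, V_i = -75, V_r = -70,
                       V_th = -50, V_reset = -70, g_l = 1, t_refract = 2,
                       tau_adapt = NULL, I_adapt_base = NULL,
                       background_ge = NULL, background_gi = NULL) {
  population <- match.arg(population)
  defaults <- switch(population,
    ORN = list(tau_adapt = 60, I_adapt_base = 40, background_ge = 0.28, background_gi = 0.5),
    PN = list(tau_adapt = 25, I_adapt_base = 4.5, background_ge = 0.24, background_gi = 0.15),
    LN = list(tau_adapt = 25, I_adapt_base = 1.8, background_ge = 0, background_gi = 0)
  )
  p <- list(
    population = population, tau_m = tau_m, V_e = V_e, V_i = V_i, V_r = V_r,
    V_th = V_th, V_reset = V_reset, g_l = g_l, t_refract = t_refract,
    tau_adapt = tau_adapt %||% defaults$tau_adapt,
    I_adapt_base = I_adapt_base %||% defaults$I_adapt_base,
    background_ge = background_ge %||% defaults$background_ge,
    background_gi = background_gi %||% defaults$background_gi
  )
  if (!(p$V_reset <= p$V_r && p$V_r < p$V_th && p$V_th < p$V_e)) {
    stop("need V_reset <= V_r < V_th < V_e", call. = FALSE)
  }
  if (p$tau_m <= 0 || p$tau_adapt <= 0) stop("time constants must be > 0", call. = FALSE)
  structure(p, class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat("<lif_params> ", x$population,
      sprintf(": tau_m %g ms, V_th %g mV, t_refract %g ms, tau_adapt %g ms\n",
              x$tau_m, x$V_th, x$t_refract, x$tau_adapt))
  invisible(x)
}

#' Membrane potential under constant conductances (closed form)
#'
#' Under the adiabatic approximation (quasi-stationary input) the
#' conductance-based LIF membrane relaxes from `V_reset` toward the effective
#' drive `I_eff = (V_e ge + V_i gi + V_r g_l) / g_total` with time constant
#' `tau_eff = tau_m / g_total`, `g_total = g_l + ge + gi`, minus a decaying
#' adaptation transient of amplitude `I_adapt_max`:
#' `V(t) = I_eff + (V_reset - I_eff) exp(-t/tau_eff)
#'  - tau_adapt I_adapt_max / (tau_adapt - tau_eff)
#'    (exp(-t/tau_adapt) - exp(-t/tau_eff))`.
#'
#' @param t time(s) since the last spike (ms).
#' @param ge,gi excitatory and inhibitory conductances (units of the leak).
#' @param params a [lif_params()].
#' @param I_adapt_max adaptation amplitude set at the spike (mV, since the
#'   membrane resistance is absorbed).
#' @return membrane potential(s), mV.
#' @export
lif_potential <- function(t, ge, gi, params, I_adapt_max = 0) {
  g_total <- params$g_l + ge + gi
  I_eff <- (params$V_e * ge + params$V_i * gi + params$V_r * params$g_l) / g_total
  tau_eff <- params$tau_m / g_total
  v <- I_eff + (params$V_reset - I_eff) * exp(-t / tau_eff)
  if (any(I_adapt_max != 0)) {
    ta <- params$tau_adapt
    v <- v - ta * I_adapt_max / (ta - tau_eff) *
      (exp(-t / ta) - exp(-t / tau_eff))
  }
  v
}

#' Firing rate of the conductance-based LIF under quasi-stationary input
#'
#' Computes the time `t_thres` for the closed-form membrane potential
#' ([lif_potential()]) to reach threshold and returns
#' `rate = 1000 / (t_thres + t_refract)` Hz; 0 if threshold is never reached
#' (`I_eff <= V_th`). Vectorized over `ge`, `gi` and `I_adapt_max`.
#'
#' Without adaptation the crossing time is analytic,
#' `t = tau_eff * log((I_eff - V_reset) / (I_eff - V_th))`. With adaptation
#' the first crossing is found by scanning forward from the no-adaptation
#' crossing time (a lower bound, since the adaptation transient only lowers
#' `V`) in steps of `scan_dt`, then bisecting the bracketing interval down to
#' `refine_tol`.
#'
#' @inheritParams lif_potential
#' @param scan_dt coarse scan step (ms).
#' @param refine_tol bisection tolerance on the crossing time (ms).
#' @param t_max give up (rate 0) if no crossing by this time (ms).
#' @return firing rate(s) in Hz, bounded by `1000 / t_refract`.
#' @examples
#' lif_rate(ge = 1, gi = 0, params = lif_params("ORN")) # ~165 Hz
#' @export
lif_rate <- function(ge, gi, params, I_adapt_max = 0,
                     scan_dt = 0.05, refine_tol = 1e-9, t_max = 5000) {
  m <- max(length(ge), length(gi), length(I_adapt_max))
  ge <- rep_len(ge, m); gi <- rep_len(gi, m); Ia <- rep_len(I_adapt_max, m)
  if (any(ge < 0 | gi < 0)) stop("conductances must be >= 0", call. = FALSE)
  g_total <- params$g_l + ge + gi
  I_eff <- (params$V_e * ge + params$V_i * gi + params$V_r * params$g_l) / g_total
  tau_eff <- params$tau_m / g_total
  rate <- numeric(m)
  can_fire <- I_eff > params$V_th
  if (!any(can_fire)) return(rate)

  t0 <- rep(NA_real_, m)
  t0[can_fire] <- tau_eff[can_fire] *
    log((I_eff[can_fire] - params$V_reset) / (I_eff[can_fire] - params$V_th))

  no_adapt <- can_fire & Ia == 0
  rate[no_adapt] <- 1000 / (t0[no_adapt] + params$t_refract)

  idx <- which(can_fire & Ia != 0)
  if (length(idx)) {
    ta <- params$tau_adapt
    vfun <- function(t, j) {
      I_eff[j] + (params$V_reset - I_eff[j]) * exp(-t / tau_eff[j]) -
        ta * Ia[j] / (ta - tau_eff[j]) * (exp(-t / ta) - exp(-t / tau_eff[j]))
    }
    # coarse forward scan from the no-adaptation lower bound
    tcur <- t0[idx]
    cross <- rep(NA_real_, length(idx))
    active <- seq_along(idx)
    while (length(active)) {
      v <- vfun(tcur[active], idx[active])
      hit <- v >= params$V_th
      if (any(hit)) {
        cross[active[hit]] <- tcur[active[hit]]
        active <- active[!hit]
      }
      tcur[active] <- tcur[active] + scan_dt
      active <- active[tcur[active] <= t_max]
    }
    ok <- which(!is.na(cross))
    if (length(ok)) {
      lo <- pmax(cross[ok] - scan_dt, 0)
      hi <- cross[ok]
      jj <- idx[ok]
      while (max(hi - lo) > refine_tol) {
        mid <- (lo + hi) / 2
        up <- vfun(mid, jj) >= params$V_th
        hi[up] <- mid[up]
        lo[!up] <- mid[!up]
      }
      rate[jj] <- 1000 / ((lo + hi) / 2 + params$t_refract)
    }
  }
  rate
}

#' Resting potential under background conductances
#'
#' The fixed point of the membrane equation with `I_adapt = 0`:
#' `V_mean = (V_e ge + V_i gi + V_r g_l) / g_total`. Used as the initial
#' membrane potential for first-spike latency calculations.
#'
#' @param params a [lif_params()]; its `background_ge`/`background_gi` are
#'   used unless overridden.
#' @param ge,gi conductance overrides.
#' @return scalar potential, mV.
#' @export
lif_resting_potential <- function(params, ge = params$background_ge,
                                  gi = params$background_gi) {
  g_total <- params$g_l + ge + gi
  (params$V_e * ge + params$V_i * gi + params$V_r * params$g_l) / g_total
}

`%||%` <- function(a, b) if (is.null(a)) b else a
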