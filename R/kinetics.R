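#' Mixture binding-rate factor w(n)
#'
#' For a mixture whose components bind with rates `k1_i` at concentrations
#' `c_i`, the overall depletion of free receptors proceeds at
#' `(sum(k1_i * c_i))^n` while each component's share keeps the ratio of the
#' single-odorant rates. The factor
#' `w(n) = (sum(k1_j c_j))^n / sum((k1_j c_j)^n)` rescales the per-component
#' binding terms so that a pure odorant split into identical "components" is
#' indistinguishable from the un-split odorant (self-mixture consistency).
#'
#' For `N` identical components `w = N^(n-1)`; for a single component or
#' `n = 1` it is exactly 1.
#'
#' @param k1 binding rate constants of the components (ms^-1).
#' @param conc component concentrations (dimensionless), recycled against `k1`.
#' @param n shared Hill coefficient (> 0).
#' @return scalar `w`. If every `k1*c` is zero, no binding occurs and `w` is
#'   returned as 1 by convention (with a message).
#' @examples
#' w_factor(c(1, 1), c(0.5, 0.5), n = 0.5) # 2^(-0.5)
#' @export
w_factor <- function(k1, conc, n) {
  if (length(n) != 1 || !is.finite(n) || n <= 0) {
    stop("`n` must be a single positive number", call. = FALSE)
  }
  b <- k1 * rep_len(conc, length(k1))
  if (any(b < 0)) stop("binding terms k1*c must be >= 0", call. = FALSE)
  if (all(b == 0)) {
    message("all component concentrations are zero; w(n) set to 1 by convention")
    return(1)
  }
  sum(b)^n / sum(b^n)
}

#' Steady-state receptor activation for a single odorant
#'
#' Closed-form steady state of the two-stage model:
#' `rstar = 1 / (1/K2prime + 1/(Keff * c^n))`. The activated fraction rises
#' from `Keff * c^n` at low concentration to the plateau `K2prime` at high
#' concentration.
#'
#' @param params tibble of rate constants, one row per odor-receptor
#'   combination (see [rate_constants()]).
#' @param conc concentration(s), >= 0; recycled against rows of `params`, or,
#'   for a one-row `params`, evaluated at every concentration.
#' @return numeric vector of activated fractions (one per row of `params`, or
#'   one per concentration for a single combination).
#' @examples
#' p <- rate_constants(1.2, 0.03, 0.1, 0.2, 0.65)
#' steady_state(p, conc = 10^seq(-4, -1))
#' @export
steady_state <- function(params, conc) {
  if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  d <- derive_constants(params)
  if (nrow(d) == 1) {
    ceff <- conc^d$n
  } else {
    ceff <- rep_len(conc, nrow(d))^d$n
  }
  ifelse(ceff == 0, 0, 1 / (1 / d$K2prime + 1 / (d$Keff * ceff)))
}

#' Effective steady-state constants of a mixture
#'
#' For components sharing the Hill coefficient `n` at concentrations `conc`,
#' computes the constants that make the mixture steady state formally identical
#' to a single odorant's: `rstar_mix = 1/(1/K2mixprime + 1/(Keffmix * ceff))`.
#'
#' `Keffmix * ceff = w * sum(Keff_i * c_i^n)` is the pooled low-concentration
#' gain; `K2mixprime = 1/sum(p_i / K2prime_i)` is the weighted harmonic mean of
#' the component plateaus with competition weights
#' `p_i = Keff_i c_i^n / sum(Keff_j c_j^n)` (each ligand's share of bound
#' receptors at saturation is set by its low-concentration gain). For equal
#' concentrations the weights reduce to `p_i = Keff_i / sum(Keff_j)` and
#' `Keffmix = w(n) * sum(Keff_i)`.
#'
#' @param params tibble of rate constants for the components of one mixture
#'   (>= 1 row); all rows must share `n`.
#' @param conc per-component concentrations (recycled); not all zero. Defaults
#'   to equal unit concentrations, for which `Keffmix` and `K2mixprime` are
#'   concentration-independent.
#' @return one-row tibble with columns `n`, `w`, `Keffmix`, `K2mixprime`, and a
#'   list-column `p` of the competition weights (summing to 1).
#' @examples
#' p <- rate_constants(k1 = c(1, 2), k_minus1 = c(0.02, 0.05),
#'                     k2 = c(0.1, 0.1), k_minus2 = c(0.2, 0.1), n = 0.65)
#' mixture_constants(p)
#' @export
mixture_constants <- function(params, conc = 1) {
  d <- derive_constants(params)
  if (length(unique(d$n)) != 1) {
    stop("mixture components must share the Hill coefficient n ",
         "(n reflects the receptor, not the odorant)", call. = FALSE)
  }
  n <- d$n[1]
  conc <- rep_len(conc, nrow(d))
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (all(conc == 0)) stop("at least one component concentration must be > 0", call. = FALSE)
  w <- w_factor(d$k1, conc, n)
  gain_i <- d$Keff * conc^n
  p <- gain_i / sum(gain_i)
  K2mixprime <- 1 / sum(p / d$K2prime)
  # Keffmix defined against ceff = mean(c)^n so that identical components
  # reduce exactly to the single-odorant constants at the summed concentration
  ceff <- mean(conc)^n
  tibble::tibble(
    n = n, w = w,
    Keffmix = w * sum(gain_i) / ceff,
    K2mixprime = K2mixprime,
    p = list(p)
  )
}

#' Steady-state receptor activation for a mixture
#'
#' General steady state of the mixture model (any component concentrations):
#' `rstar_total = w * sum(Keff_i c_i^n) / (1 + w * sum(K1_i (1 + K2_i) c_i^n))`,
#' with per-component activated fractions
#' `rstar_i = w * Keff_i * c_i^n * r0`. For equal component concentrations this
#' equals the closed form built from [mixture_constants()].
#'
#' @inheritParams mixture_constants
#' @param legacy if `TRUE`, use the earlier two-stage mixture model that omits
#'   the `w(n)` factor and depletes free receptors at `sum((k1_j c_j)^n)`; that
#'   variant is not self-mixture consistent and is kept for comparison.
#' @return one-row tibble with `rstar_total`, `r0`, and list-columns `rstar`
#'   and `r` of per-component activated and bound fractions.
#' @examples
#' p <- rate_constants(k1 = c(1, 2), k_minus1 = c(0.02, 0.05),
#'                     k2 = c(0.1, 0.1), k_minus2 = c(0.2, 0.1), n = 0.65)
#' steady_state_mixture(p, conc = 0.01)
#' @export
steady_state_mixture <- function(params, conc = 1, legacy = FALSE) {
  d <- derive_constants(params)
  if (length(unique(d$n)) != 1) {
    stop("mixture components must share the Hill coefficient n", call. = FALSE)
  }
  n <- d$n[1]
  conc <- rep_len(conc, nrow(d))
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (all(conc == 0)) {
    zero <- rep(0, nrow(d))
    return(tibble::tibble(rstar_total = 0, r0 = 1, rstar = list(zero), r = list(zero)))
  }
  w <- if (legacy) 1 else w_factor(d$k1, conc, n)
  ci_n <- conc^n
  r0 <- 1 / (1 + w * sum(d$K1 * (1 + d$K2) * ci_n))
  r_i <- w * d$K1 * ci_n * r0
  rstar_i <- d$K2 * r_i
  tibble::tibble(
    rstar_total = sum(rstar_i), r0 = r0,
    rstar = list(rstar_i), r = list(r_i)
  )
}

#' Short-time receptor activation after stimulus onset
#'
#' In the limit of small time and concentration the activated fraction grows
#' quadratically: `rstar(t) ~ keff * ceff * t^2 / 2` with
#' `keff = k1^n * k2` for a single odorant, and
#' `rstar_mix(t) ~ w(n) * sum(keff_i * c_i^n) * t^2 / 2` for a mixture. This
#' initial ramp is what sets first-spike latencies.
#'
#' @inheritParams mixture_constants
#' @param t time(s) after onset, ms.
#' @param legacy if `TRUE`, drop the `w(n)` factor (previous model variant).
#' @return numeric vector of approximate total activated fractions, one per
#'   value of `t`.
#' @examples
#' p <- rate_constants(1, 0.001, 0.1, 0.2, n = 1)
#' initial_activation(p, conc = 0.01, t = 1) # 0.1 * 0.01 / 2
#' @export
initial_activation <- function(params, conc, t, legacy = FALSE) {
  d <- derive_constants(params)
  if (length(unique(d$n)) != 1) {
    stop("mixture components must share the Hill coefficient n", call. = FALSE)
  }
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  n <- d$n[1]
  conc <- rep_len(conc, nrow(d))
  if (all(conc == 0)) return(rep(0, length(t)))
  w <- if (legacy) 1 else w_factor(d$k1, conc, n)
  w * sum(d$keff_rate * conc^n) * t^2 / 2
}

#' Classify the mixture interaction regime
#'
#' At low concentration the sign of the mixture interaction is set entirely by
#' the Hill coefficient: `n > 1` gives synergy (mixture response exceeds the
#' sum of component responses), `n = 1` strict additivity, and `0 < n < 1`
#' hypoadditivity. At high concentration the mixture plateau is the weighted
#' harmonic mean of the component plateaus, so the interaction is hypoadditive
#' regardless of `n`.
#'
#' @param n Hill coefficient(s), > 0.
#' @param regime `"low_c"` or `"high_c"`.
#' @return character vector: `"synergistic"`, `"additive"` or `"hypoadditive"`.
#' @examples
#' classify_interaction(c(0.65, 1, 1.5), "low_c")
#' classify_interaction(0.65, "high_c")
#' @export
classify_interaction <- function(n, regime = c("low_c", "high_c")) {
  regime <- match.arg(regime)
  if (any(!is.finite(n) | n <= 0)) {
    stop("Hill coefficient n must be > 0", call. = FALSE)
  }
  if (regime == "high_c") return(rep("hypoadditive", length(n)))
  dplyr::case_when(
    n > 1 ~ "synergistic",
    n == 1 ~ "additive",
    TRUE ~ "hypoadditive"
  )
}

#' Reduce an N-component mixture to a nested binary representation
#'
#' An equal-concentration mixture of `N` components can be treated as a binary
#' mixture of (i) a pseudo-odorant summarising the first `N - 1` components and
#' (ii) the last component, recursively. The pseudo-odorant is characterised by
#' the effective constants `Keff_prime` (its pooled low-concentration gain,
#' before the mixture `w` correction) and `K2_doubleprime` (its plateau, the
#' weighted harmonic mean of its components' plateaus), plus two binding sums
#' needed to evaluate `w` exactly at the outer level: the linear sum
#' `sum(k1_j)` and the power sum `sum(k1_j^n)`. Carrying `(sum k1_j)^n` alone
#' in place of the power sum does not reproduce the direct N-component steady
#' state; with both sums the recursion is exact.
#'
#' @param params tibble of rate constants (>= 2 rows, shared `n`); components
#'   are taken at equal concentrations.
#' @return an object of class `"mixture_reduction"`: a list with the outer
#'   component (`outer`), the inner pseudo-odorant's effective constants
#'   (`inner`: `Keff_prime`, `K2_doubleprime`, `k1_linear_sum`,
#'   `k1n_power_sum`), the shared `n`, and the nested reduction of the inner
#'   mixture (`inner_reduction`, `NULL` once binary). For `N = 2` the inner
#'   pseudo-odorant is just the first component.
#' @seealso [nested_steady_state()] to evaluate the representation.
#' @export
reduce_mixture <- function(params) {
  d <- derive_constants(params)
  if (nrow(d) < 2) stop("need at least two components", call. = FALSE)
  if (length(unique(d$n)) != 1) {
    stop("mixture components must share the Hill coefficient n", call. = FALSE)
  }
  n <- d$n[1]
  inner_rows <- d[-nrow(d), ]
  inner <- list(
    Keff_prime = sum(inner_rows$Keff),
    K2_doubleprime = sum(inner_rows$Keff) / sum(inner_rows$Keff / inner_rows$K2prime),
    k1_linear_sum = sum(inner_rows$k1),
    k1n_power_sum = sum(inner_rows$k1^n)
  )
  structure(
    list(
      outer = d[nrow(d), ],
      inner = inner,
      n = n,
      inner_reduction = if (nrow(inner_rows) >= 2) reduce_mixture(inner_rows) else NULL
    ),
    class = "mixture_reduction"
  )
}

#' Steady state of a nested binary mixture representation
#'
#' Applies the binary mixture formulas to a [reduce_mixture()] object: the
#' binary `w` is evaluated with the pseudo-odorant's linear and power binding
#' sums, the pooled gain is `w * (Keff_prime + Keff_outer) * c^n`, and the
#' plateau is the `p`-weighted harmonic mean of `K2_doubleprime` and the outer
#' component's plateau. Equal to the direct N-component
#' [steady_state_mixture()] up to floating-point error.
#'
#' @param reduction a `"mixture_reduction"` object.
#' @param conc common per-component concentration (scalar, > 0).
#' @return activated fraction (scalar).
#' @export
nested_steady_state <- function(reduction, conc) {
  stopifnot(inherits(reduction, "mixture_reduction"), length(conc) == 1, conc >= 0)
  if (conc == 0) return(0)
  n <- reduction$n
  inner <- reduction$inner
  outer <- reduction$outer
  w <- (inner$k1_linear_sum + outer$k1)^n / (inner$k1n_power_sum + outer$k1^n)
  gains <- c(inner$Keff_prime, outer$Keff) * conc^n
  p <- gains / sum(gains)
  K2p <- c(inner$K2_doubleprime, outer$K2prime)
  K2mixprime <- 1 / sum(p / K2p)
  1 / (1 / K2mixprime + 1 / (w * sum(gains)))
}

#' @export
print.mixture_reduction <- function(x, ...) {
  n_comp <- 1
  r <- x
  while (!is.null(r)) {
    n_comp <- n_comp + 1
    r <- r$inner_reduction
  }
  cat("Nested binary representation of a", n_comp, "component mixture\n")
  cat("  inner pseudo-odorant: Keff' =", signif(x$inner$Keff_prime, 4),
      " K2'' =", signif(x$inner$K2_doubleprime, 4), "\n")
  invisible(x)
}
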