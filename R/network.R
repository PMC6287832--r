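#' Pearson correlation between two response patterns
#'
#' Thin wrapper around [stats::cor()] that flags degenerate (zero-variance)
#' patterns instead of silently returning `NA`.
#'
#' @param x,y numeric vectors of equal length.
#' @return Pearson correlation in `[-1, 1]`, or `NA` (with a warning) if
#'   either pattern has zero variance.
#' @export
pattern_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("patterns must have equal length", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance pattern: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

draw_bounded_normal <- function(m, mean, sd) {
  # jittered weights stay within mean +/- 2 sd (hard boundary)
  x <- stats::rnorm(m, mean, sd)
  bad <- abs(x - mean) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > 2 * sd
  }
  x
}

#' Build the antennal lobe network
#'
#' Constructs the 160-glomerulus network: each glomerulus holds one ORN type,
#' one PN and one LN. ORNs excite their glomerulus' PN and LN with uniform,
#' jittered weights; LNs inhibit the PNs and LNs of *other* glomeruli with
#' weights that grow with the similarity of the two glomeruli's odor tuning:
#' `w_ij = (1 - delta_ij) * s_ij * (w0_ij + H(rho_ij) * rho_ij * wcorr_ij)`,
#' where `rho_ij` is the Pearson correlation between the ORN response
#' patterns of glomeruli `i` and `j` across odors at high concentration
#' (`c = 0.3`), `H` the Heaviside function, and `s_ij` a jittered per-type
#' synaptic gain (LN->PN and LN->LN scales). All normal draws are jittered
#' within mean +/- 2 sd.
#'
#' @param activation an `"activation_matrix"` (defines odor tuning).
#' @param seed integer seed for the weight draws.
#' @param params optional rate-constant table; defaults to
#'   [activation_to_params()] of `activation`.
#' @param g_orn ORN receptor-conductance scale (nS).
#' @param weights named list overriding the published connectivity constants
#'   `w0 = (0.006, 0.002)`, `wcorr = (0.01, 0.001)`, `orn_pn = (0.045, 0.01)`,
#'   `orn_ln = (0.013, 0.003)`, `ln_pn = (0.04, 0.01)`,
#'   `ln_ln = (0.004, 0.001)` (each `(mean, sd)`).
#' @return object of class `"al_network"`.
#' @export
build_network <- function(activation, seed = 1, params = NULL, g_orn = 2,
                          weights = list()) {
  stopifnot(inherits(activation, "activation_matrix"))
  set.seed(seed)
  wdef <- list(w0 = c(0.006, 0.002), wcorr = c(0.01, 0.001),
               orn_pn = c(0.045, 0.01), orn_ln = c(0.013, 0.003),
               ln_pn = c(0.04, 0.01), ln_ln = c(0.004, 0.001))
  wdef[names(weights)] <- weights
  params <- params %||% activation_to_params(activation)
  n_g <- nrow(activation$gmax)

  # odor tuning at high concentration -> ORN-ORN pattern correlations
  d <- derive_constants(params)
  resp_high <- matrix(steady_state(d, 0.3), n_g)
  rho <- suppressWarnings(stats::cor(t(resp_high)))
  rho[!is.finite(rho)] <- 0

  eq7 <- function(scale_spec) {
    w0 <- matrix(draw_bounded_normal(n_g^2, wdef$w0[1], wdef$w0[2]), n_g)
    wc <- matrix(draw_bounded_normal(n_g^2, wdef$wcorr[1], wdef$wcorr[2]), n_g)
    s <- matrix(draw_bounded_normal(n_g^2, scale_spec[1], scale_spec[2]), n_g)
    w <- s * (w0 + (rho > 0) * rho * wc)
    diag(w) <- 0
    w
  }
  structure(list(
    n_glomeruli = n_g,
    params = params,
    activation = activation,
    rho = rho,
    g_orn = g_orn,
    w_ln_pn = eq7(wdef$ln_pn),
    w_ln_ln = eq7(wdef$ln_ln),
    w_orn_pn = draw_bounded_normal(n_g, wdef$orn_pn[1], wdef$orn_pn[2]),
    w_orn_ln = draw_bounded_normal(n_g, wdef$orn_ln[1], wdef$orn_ln[2]),
    lif = list(ORN = lif_params("ORN"), PN = lif_params("PN"), LN = lif_params("LN")),
    bg_pn_ge = draw_bounded_normal(n_g, 0.24, 0.02),
    bg_pn_gi = draw_bounded_normal(n_g, 0.15, 0.01),
    I_adapt_pn = draw_bounded_normal(n_g, 4.5, 0.4),
    I_adapt_ln = draw_bounded_normal(n_g, 1.8, 0.2),
    seed = seed
  ), class = "al_network")
}

#' @export
print.al_network <- function(x, ...) {
  cat("<al_network> ", x$n_glomeruli, " glomeruli, seed ", x$seed, "\n", sep = "")
  cat(sprintf("  LN->PN weights: mean %.2g (zero diagonal), LN->LN mean %.2g\n",
              mean(x$w_ln_pn[upper.tri(x$w_ln_pn)]),
              mean(x$w_ln_ln[upper.tri(x$w_ln_ln)])))
  invisible(x)
}

#' Per-glomerulus receptor activation for a set of stimuli
#'
#' For each stimulus (a named list with `odors`, a vector of odor ids, and
#' `conc`, the per-component concentrations) computes the steady-state total
#' activated receptor fraction of every glomerulus from the network's
#' rate-constant table.
#'
#' @param net an `"al_network"` (or a rate-constant tibble with `odor_id` and
#'   `receptor_id` columns).
#' @param stimuli list of stimuli; each element a list
#'   `list(odors = c("odor1", "odor3"), conc = 0.01)` (`conc` recycled over
#'   components).
#' @param legacy use the legacy (non-consistent) mixture model.
#' @return matrix glomeruli x stimuli of activated fractions.
#' @export
receptor_drive <- function(net, stimuli, legacy = FALSE) {
  params <- if (inherits(net, "al_network")) net$params else net
  d <- derive_constants(params)
  receptors <- unique(d$receptor_id)
  out <- matrix(0, length(receptors), length(stimuli),
                dimnames = list(receptors, NULL))
  for (s in seq_along(stimuli)) {
    st <- stimuli[[s]]
    rows <- d[d$odor_id %in% st$odors, ]
    conc <- rep_len(st$conc, length(st$odors))
    conc_by_row <- conc[match(rows$odor_id, st$odors)]
    n <- rows$n # per receptor (shared within receptor)
    ci_n <- conc_by_row^n
    b <- rows$k1 * conc_by_row
    grp <- match(rows$receptor_id, receptors)
    if (legacy) {
      w <- rep(1, length(receptors))
    } else {
      sum_b <- rowsum(b, grp)[, 1]
      sum_bn <- rowsum(b^rows$n, grp)[, 1]
      n_by_rec <- rowsum(rows$n, grp)[, 1] / tabulate(grp, length(receptors))
      w <- ifelse(sum_b > 0, sum_b^n_by_rec / sum_bn, 1)
    }
    gain <- rowsum(rows$Keff * ci_n, grp)[, 1]
    depl <- rowsum(rows$K1 * (1 + rows$K2) * ci_n, grp)[, 1]
    out[, s] <- w * gain / (1 + w * depl)
  }
  out
}

#' Simulate the antennal lobe network to its rate fixed point
#'
#' Quasi-stationary rate dynamics: each unit's firing rate is the
#' conductance-based LIF rate ([lif_rate()]) of its instantaneous synaptic
#' input, with conductances proportional to presynaptic rates (in Hz) and
#' adaptation amplitudes set by the presynaptic drive (receptor activation
#' for ORNs, the unit's own rate in spikes/ms for PNs and LNs). ORN rates are
#' computed once; PN and LN rates are iterated synchronously (one-step lag)
#' with damping until the fixed point.
#'
#' @param net an `"al_network"`.
#' @param stimuli as in [receptor_drive()]; alternatively supply `drive`.
#' @param drive optional precomputed glomeruli x stimuli activation matrix.
#' @param legacy passed to [receptor_drive()].
#' @param damping update damping factor in (0, 1].
#' @param max_iter,tol fixed-point iteration controls (tol in Hz).
#' @param lesion_ln_pn set all LN->PN weights to zero (lateral-inhibition
#'   lesion control).
#' @return object of class `"al_response"`: list of matrices `orn`, `pn`,
#'   `ln` (glomeruli x stimuli, Hz), plus `converged` per stimulus.
#' @export
simulate_network <- function(net, stimuli = NULL, drive = NULL, legacy = FALSE,
                             damping = 0.5, max_iter = 200, tol = 0.01,
                             lesion_ln_pn = FALSE) {
  stopifnot(inherits(net, "al_network"))
  if (is.null(drive)) {
    if (is.null(stimuli)) stop("supply `stimuli` or `drive`", call. = FALSE)
    drive <- receptor_drive(net, stimuli, legacy = legacy)
  }
  n_g <- net$n_glomeruli
  n_s <- ncol(drive)
  p_orn <- net$lif$ORN; p_pn <- net$lif$PN; p_ln <- net$lif$LN
  w_lp <- if (lesion_ln_pn) matrix(0, n_g, n_g) else net$w_ln_pn

  orn <- matrix(0, n_g, n_s); pn <- matrix(0, n_g, n_s); ln <- matrix(0, n_g, n_s)
  converged <- logical(n_s)
  for (s in seq_len(n_s)) {
    r <- drive[, s]
    nu_orn <- lif_rate(ge = net$g_orn * r + p_orn$background_ge,
                       gi = p_orn$background_gi, params = p_orn,
                       I_adapt_max = p_orn$I_adapt_base * r)
    nu_pn <- rep(0, n_g); nu_ln <- rep(0, n_g)
    for (it in seq_len(max_iter)) {
      gi_ln <- as.vector(net$w_ln_ln %*% nu_ln)
      new_ln <- lif_rate(ge = net$w_orn_ln * nu_orn, gi = gi_ln, params = p_ln,
                         I_adapt_max = net$I_adapt_ln * nu_ln / 1000)
      gi_pn <- as.vector(w_lp %*% nu_ln)
      new_pn <- lif_rate(ge = net$w_orn_pn * nu_orn + net$bg_pn_ge,
                         gi = gi_pn + net$bg_pn_gi, params = p_pn,
                         I_adapt_max = net$I_adapt_pn * nu_pn / 1000)
      delta <- max(abs(new_ln - nu_ln), abs(new_pn - nu_pn))
      nu_ln <- nu_ln + damping * (new_ln - nu_ln)
      nu_pn <- nu_pn + damping * (new_pn - nu_pn)
      if (delta < tol) break
    }
    converged[s] <- delta < tol
    orn[, s] <- nu_orn; pn[, s] <- nu_pn; ln[, s] <- nu_ln
  }
  if (!all(converged)) {
    warning(sum(!converged), " stimulus/stimuli did not reach the rate fixed point",
            call. = FALSE)
  }
  structure(list(orn = orn, pn = pn, ln = ln, converged = converged,
                 drive = drive),
            class = "al_response")
}

#' @export
print.al_response <- function(x, ...) {
  cat("<al_response> ", nrow(x$orn), " glomeruli x ", ncol(x$orn), " stimuli\n",
      sep = "")
  cat(sprintf("  mean rates (Hz): ORN %.1f, PN %.1f, LN %.1f\n",
              mean(x$orn), mean(x$pn), mean(x$ln)))
  invisible(x)
}

#' Cross-concentration pattern correlation
#'
#' Pearson correlation, across units, between a stimulus's response pattern
#' at a low and at a high concentration — the pattern-stability measure. Works
#' on `"al_response"` objects (choose the population) or plain matrices with
#' matched columns.
#'
#' @param resp_low,resp_high responses at the two concentrations: matrices
#'   (units x stimuli) or `"al_response"` objects.
#' @param population which population to use for `"al_response"` inputs.
#' @return tibble with `stimulus` and `correlation`.
#' @export
cross_concentration_correlation <- function(resp_low, resp_high,
                                            population = c("orn", "pn", "ln")) {
  population <- match.arg(population)
  low <- if (inherits(resp_low, "al_response")) resp_low[[population]] else resp_low
  high <- if (inherits(resp_high, "al_response")) resp_high[[population]] else resp_high
  if (!all(dim(low) == dim(high))) {
    stop("response matrices must have matched units and stimuli", call. = FALSE)
  }
  tibble::tibble(
    stimulus = seq_len(ncol(low)),
    correlation = vapply(seq_len(ncol(low)), function(s) {
      pattern_correlation(low[, s], high[, s])
    }, numeric(1))
  )
}
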