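#' ORN firing rate from receptor activation (ensemble studies)
#'
#' Maps steady-state receptor activation to an ORN firing rate through the
#' conductance-based LIF with the published ORN parameters:
#' `ge = g_orn * rstar`, `gi = 0`, adaptation amplitude
#' `I_adapt_base * rstar`. Background conductances are deliberately omitted
#' in the abstract ensemble studies: they model spontaneous antennal-lobe
#' input, and with them every unit sits just below threshold regardless of
#' stimulus, which erases the thresholding that distinguishes weak from
#' silent combinations (see the methods vignette).
#'
#' @param rstar activated receptor fraction(s).
#' @param g_orn receptor conductance scale (nS).
#' @param lif ORN [lif_params()]; its background fields are ignored here.
#' @param adaptation include the adaptation amplitude `I_adapt_base * rstar`.
#' @return firing rate(s), Hz.
#' @export
orn_rate_map <- function(rstar, g_orn = 2, lif = lif_params("ORN"),
                         adaptation = TRUE) {
  lif_rate(ge = g_orn * rstar, gi = 0, params = lif,
           I_adapt_max = if (adaptation) lif$I_adapt_base * rstar else 0)
}

table1_trial <- function(spec, level, c_low, c_high, rate_map) {
  d <- derive_constants(sample_ensemble(spec))
  m <- spec$pop_size
  iA <- seq(1, 2 * m, by = 2)
  iB <- iA + 1
  n <- d$n[iA]
  if (level == "constants") {
    w <- (d$k1[iA] + d$k1[iB])^n / (d$k1[iA]^n + d$k1[iB]^n)
    Keffmix <- w * (d$Keff[iA] + d$Keff[iB])
    p1 <- d$Keff[iA] / (d$Keff[iA] + d$Keff[iB])
    K2mixprime <- 1 / (p1 / d$K2prime[iA] + (1 - p1) / d$K2prime[iB])
    stats::cor(Keffmix, K2mixprime) - stats::cor(d$Keff, d$K2prime)
  } else {
    rstar_single <- function(cc) 1 / (1 / d$K2prime + 1 / (d$Keff * cc^d$n))
    rstar_mix <- function(cc) {
      ci_n <- cc^n
      w <- (d$k1[iA] + d$k1[iB])^n / (d$k1[iA]^n + d$k1[iB]^n)
      gain <- (d$Keff[iA] + d$Keff[iB]) * ci_n
      depl <- (d$K1[iA] * (1 + d$K2[iA]) + d$K1[iB] * (1 + d$K2[iB])) * ci_n
      w * gain / (1 + w * depl)
    }
    s_lo <- rate_map(rstar_single(c_low)); s_hi <- rate_map(rstar_single(c_high))
    m_lo <- rate_map(rstar_mix(c_low)); m_hi <- rate_map(rstar_mix(c_high))
    suppressWarnings(pattern_correlation(m_lo, m_hi) -
                       pattern_correlation(s_lo, s_hi))
  }
}

#' Monte-Carlo correlation study: mixtures vs single odorants
#'
#' For each trial, samples a population of odor-receptor combinations and
#' compares how well the low- and high-concentration response patterns
#' correlate for binary mixtures versus single odorants.
#'
#' * `level = "constants"`: the patterns are the asymptotic determinants
#'   themselves — the difference between `cor(Keffmix, K2mixprime)` across
#'   the paired mixtures and `cor(Keff, K2prime)` across all single
#'   combinations.
#' * `level = "orn_rate"`: steady-state activations at `c_low` and `c_high`
#'   are mapped to ORN firing rates ([orn_rate_map()]); the difference of the
#'   cross-concentration Pearson correlations (mixtures minus singles) is
#'   reported.
#'
#' A trial is *discordant* when the mixture correlation is not higher than
#' the single-odorant one (difference <= 0).
#'
#' @param spec an [ensemble_spec()] (see [ensemble_spec_table1()]).
#' @param level `"constants"` or `"orn_rate"`.
#' @param n_trials Monte-Carlo trials.
#' @param c_low,c_high the two concentrations compared at `"orn_rate"` level.
#' @param seed optional integer seed.
#' @param rate_map function mapping activated fraction to rate (ORN-rate
#'   level only).
#' @return object of class `"table1_result"`: list with the per-trial
#'   differences (`differences`), `mean_corr_difference`,
#'   `discordant_fraction` and the run settings.
#' @examples
#' run_table1(ensemble_spec_table1("uniform"), n_trials = 20, seed = 1)
#' @export
run_table1 <- function(spec, level = c("constants", "orn_rate"),
                       n_trials = 1000, c_low = 1e-4, c_high = 1e-1,
                       seed = NULL, rate_map = orn_rate_map) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  diffs <- vapply(seq_len(n_trials), function(i) {
    table1_trial(spec, level, c_low, c_high, rate_map)
  }, numeric(1))
  if (any(!is.finite(diffs))) {
    stop("degenerate ensemble: undefined correlations in ",
         sum(!is.finite(diffs)), " trial(s)", call. = FALSE)
  }
  structure(list(
    differences = diffs,
    mean_corr_difference = mean(diffs),
    discordant_fraction = mean(diffs <= 0),
    level = level, n_trials = n_trials, c_low = c_low, c_high = c_high,
    spec = spec, seed = seed
  ), class = "table1_result")
}

#' @export
print.table1_result <- function(x, ...) {
  cat("<table1_result> level =", x$level, "(", x$n_trials, "trials )\n")
  cat(sprintf("  mean correlation difference (mixture - single): %.4f\n",
              x$mean_corr_difference))
  cat(sprintf("  discordant trials: %.1f%%\n", 100 * x$discordant_fraction))
  invisible(x)
}

#' Dose-response curves of average ORN and PN rates
#'
#' Simulates the antennal lobe network over a concentration grid for
#' single odorants, binary and ternary mixtures (all components at the same
#' concentration) and returns population-average firing rates. At low
#' concentration the average mixture response exceeds the single-odorant
#' response but stays below `N` times it (hypoadditivity at the population
#' level, since most Hill coefficients are < 1); at high concentration the
#' averages nearly coincide.
#'
#' @param net an `"al_network"`.
#' @param conc concentration grid (per component).
#' @param n_components component counts to simulate (subset of 1:3).
#' @param n_sets how many random odor sets per component count.
#' @param seed seed for the odor-set draws.
#' @return tibble with `concentration`, `n_components`, `population`
#'   (`"ORN"`/`"PN"`), `rate_hz` (grand average over glomeruli and odor
#'   sets).
#' @export
run_dose_response <- function(net, conc = 10^seq(-5, -0.5, by = 0.5),
                              n_components = 1:3, n_sets = 8, seed = 1) {
  stopifnot(inherits(net, "al_network"))
  set.seed(seed)
  odors <- unique(net$params$odor_id)
  out <- list()
  for (nc in n_components) {
    sets <- lapply(seq_len(n_sets), function(i) sample(odors, nc))
    for (cc in conc) {
      stimuli <- lapply(sets, function(o) list(odors = o, conc = cc))
      resp <- simulate_network(net, stimuli)
      out[[length(out) + 1]] <- tibble::tibble(
        concentration = cc, n_components = nc,
        population = c("ORN", "PN"),
        rate_hz = c(mean(resp$orn), mean(resp$pn))
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Pattern stability across concentrations: component count and mixture ratio
#'
#' ORN-level cross-concentration correlation study on sampled parameter
#' ensembles, reproducing two observations: (i) the correlation between the
#' low- and high-concentration rate patterns increases with the number of
#' mixture components (molecule-matched: an N-component stimulus has each
#' component at `c_total/N`), in every trial; and (ii) for binary mixtures
#' the effect shrinks smoothly as the component ratio becomes unbalanced,
#' reaching the single-odorant value at ratio 1:0. Both the consistent and
#' the legacy receptor model show the effects.
#'
#' @param spec an [ensemble_spec()].
#' @param counts component counts for the monotonicity part.
#' @param fractions first-component fractions `f` for the ratio part (binary
#'   mixture at `f*c_total` and `(1-f)*c_total`).
#' @param c_low,c_high total-stimulus concentrations compared.
#' @param n_trials Monte-Carlo trials.
#' @param n_sets independent stimulus sets per trial; the reported per-trial
#'   correlation is the average over the sets (the per-trial values of the
#'   underlying study are averages over its whole odor panel, which is what
#'   makes the count-monotonicity hold trial by trial).
#' @param model `"consistent"` or `"legacy"`.
#' @param seed optional seed.
#' @param rate_map activation-to-rate map.
#' @return list of class `"stability_result"` with tibbles `by_count`
#'   (per trial and count) and `by_ratio` (per trial and fraction).
#' @export
run_pattern_stability <- function(spec, counts = 1:3,
                                  fractions = c(0.5, 0.75, 0.9, 0.99, 1),
                                  c_low = 3e-4, c_high = 3e-1,
                                  n_trials = 50, n_sets = 1,
                                  model = c("consistent", "legacy"),
                                  seed = NULL, rate_map = orn_rate_map) {
  model <- match.arg(model)
  legacy <- model == "legacy"
  if (!is.null(seed)) set.seed(seed)
  m <- spec$pop_size
  max_k <- max(max(counts), 2)
  stride <- max_k * n_sets
  by_count <- list(); by_ratio <- list()
  for (tr in seq_len(n_trials)) {
    d <- derive_constants(sample_ensemble(spec, n_odors = stride))
    n_rec <- d$n[seq(1, nrow(d), by = stride)]
    mix_rstar <- function(set, conc_by_comp, cc_total) {
      # conc_by_comp: per-component share of the total concentration
      b <- 0; bn <- 0; gain <- 0; depl <- 0
      for (j in seq_along(conc_by_comp)) {
        cj <- conc_by_comp[j] * cc_total
        rows <- seq((set - 1) * max_k + j, nrow(d), by = stride)
        b <- b + d$k1[rows] * cj
        bn <- bn + (d$k1[rows] * cj)^n_rec
        gain <- gain + d$Keff[rows] * cj^n_rec
        depl <- depl + d$K1[rows] * (1 + d$K2[rows]) * cj^n_rec
      }
      keep <- bn > 0
      w <- rep(1, m)
      if (!legacy) w[keep] <- (b[keep]^n_rec[keep]) / bn[keep]
      w * gain / (1 + w * depl)
    }
    corr_at <- function(shares) {
      mean(vapply(seq_len(n_sets), function(set) {
        lo <- rate_map(mix_rstar(set, shares, c_low))
        hi <- rate_map(mix_rstar(set, shares, c_high))
        suppressWarnings(pattern_correlation(lo, hi))
      }, numeric(1)))
    }
    for (nc in counts) {
      by_count[[length(by_count) + 1]] <- tibble::tibble(
        trial = tr, n_components = nc,
        correlation = corr_at(rep(1 / nc, nc))
      )
    }
    for (f in fractions) {
      by_ratio[[length(by_ratio) + 1]] <- tibble::tibble(
        trial = tr, fraction = f,
        correlation = corr_at(c(f, 1 - f))
      )
    }
  }
  structure(list(by_count = dplyr::bind_rows(by_count),
                 by_ratio = dplyr::bind_rows(by_ratio),
                 model = model, c_low = c_low, c_high = c_high),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result> model =", x$model, "\n")
  s <- x$by_count |>
    dplyr::group_by(.data$n_components) |>
    dplyr::summarise(correlation = mean(.data$correlation), .groups = "drop")
  cat("  mean cross-concentration correlation by component count:\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("    %d: %.3f\n", s$n_components[i], s$correlation[i]))
  }
  invisible(x)
}

#' First-spike latency experiment over a parameter ensemble
#'
#' Average ORN first-spike latency for single odorants, binary and ternary
#' mixtures over sampled ensembles. Molecule counts are matched: an
#' N-component stimulus has each component at concentration `c0`, and is
#' compared against single odorants at `N * c0`. Latencies are capped at 100
#' ms before averaging.
#'
#' @param spec an [ensemble_spec()].
#' @param c0 per-component concentration(s) to test.
#' @param counts component counts (subset of 1:3).
#' @param n_trials ensemble draws (each of `pop_size` receptors).
#' @param include_doubled_single also compute the single-odorant latency at
#'   `2 * c0` (the molecule-matched reference for binary mixtures).
#' @param legacy use the legacy mixture model.
#' @param seed optional seed.
#' @param ... passed to [first_spike_latency()].
#' @return tibble with `trial`, `condition`, `n_components`, `c0`,
#'   `mean_latency_ms`, `frac_capped`.
#' @export
run_latency_experiment <- function(spec, c0 = c(1e-4, 1e-3, 1e-2),
                                   counts = 1:3, n_trials = 5,
                                   include_doubled_single = TRUE,
                                   legacy = FALSE, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  max_k <- max(counts)
  out <- list()
  for (tr in seq_len(n_trials)) {
    d <- sample_ensemble(spec, n_odors = max_k)
    for (cc in c0) {
      conds <- list()
      for (nc in counts) {
        sub <- d[d$odor <= nc, ]
        sub$group <- sub$receptor_id
        res <- first_spike_latency(sub, conc = cc, legacy = legacy, ...)
        conds[[length(conds) + 1]] <- tibble::tibble(
          trial = tr, condition = paste0(nc, "-component"),
          n_components = nc, c0 = cc,
          mean_latency_ms = mean(res$latency_ms),
          frac_capped = mean(res$capped)
        )
      }
      if (include_doubled_single) {
        sub <- d[d$odor == 1, ]
        sub$group <- sub$receptor_id
        res <- first_spike_latency(sub, conc = 2 * cc, legacy = legacy, ...)
        conds[[length(conds) + 1]] <- tibble::tibble(
          trial = tr, condition = "single at 2x concentration",
          n_components = 1, c0 = cc,
          mean_latency_ms = mean(res$latency_ms),
          frac_capped = mean(res$capped)
        )
      }
      out[[length(out) + 1]] <- dplyr::bind_rows(conds)
    }
  }
  dplyr::bind_rows(out)
}
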