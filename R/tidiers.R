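#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Monte-Carlo correlation study
#'
#' @param x a `"table1_result"`.
#' @param ... unused.
#' @return tibble with one row per trial: `trial`, `corr_difference`,
#'   `discordant`.
#' @method tidy table1_result
#' @export
tidy.table1_result <- function(x, ...) {
  tibble::tibble(
    trial = seq_along(x$differences),
    corr_difference = x$differences,
    discordant = x$differences <= 0
  )
}

#' @rdname tidy.table1_result
#' @return `glance()`: a one-row summary with the mean correlation
#'   difference, discordant fraction and run settings.
#' @method glance table1_result
#' @export
glance.table1_result <- function(x, ...) {
  tibble::tibble(
    level = x$level,
    n_trials = x$n_trials,
    mean_corr_difference = x$mean_corr_difference,
    discordant_fraction = x$discordant_fraction,
    c_low = x$c_low,
    c_high = x$c_high
  )
}

#' @method autoplot table1_result
#' @export
autoplot.table1_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$corr_difference)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "grey20") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "cross-concentration correlation difference (mixture - single)",
      y = "trials",
      title = sprintf("Mixture patterns are more concentration-stable (%s level)",
                      object$level),
      subtitle = sprintf("mean difference %.3f; %.1f%% discordant trials",
                         object$mean_corr_difference,
                         100 * object$discordant_fraction)
    )
}

#' Tidy a pattern-stability experiment
#'
#' @param x a `"stability_result"`.
#' @param which `"count"` (component-count part) or `"ratio"` (binary
#'   ratio-imbalance part).
#' @param ... unused.
#' @return the requested per-trial tibble.
#' @method tidy stability_result
#' @export
tidy.stability_result <- function(x, which = c("count", "ratio"), ...) {
  which <- match.arg(which)
  if (which == "count") x$by_count else x$by_ratio
}

#' @method glance stability_result
#' @export
glance.stability_result <- function(x, ...) {
  cnt <- x$by_count |>
    dplyr::group_by(.data$n_components) |>
    dplyr::summarise(correlation = mean(.data$correlation), .groups = "drop")
  tibble::tibble(
    model = x$model,
    c_low = x$c_low, c_high = x$c_high,
    corr_single = cnt$correlation[cnt$n_components == 1][1],
    corr_max_count = max(cnt$correlation),
    monotone_fraction = {
      wide <- tidyr::pivot_wider(x$by_count, names_from = "n_components",
                                 values_from = "correlation")
      mat <- as.matrix(wide[, -1])
      mean(apply(mat, 1, function(r) all(diff(r) > 0)))
    }
  )
}

#' @method autoplot stability_result
#' @export
autoplot.stability_result <- function(object, which = c("count", "ratio"), ...) {
  which <- match.arg(which)
  if (which == "count") {
    df <- object$by_count |>
      dplyr::group_by(.data$n_components) |>
      dplyr::summarise(mean = mean(.data$correlation),
                       sd = stats::sd(.data$correlation), .groups = "drop")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$n_components, y = .data$mean)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                            ymax = .data$mean + .data$sd)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_continuous(breaks = unique(df$n_components)) +
      ggplot2::labs(x = "components in mixture",
                    y = "cross-concentration correlation",
                    title = "Pattern stability grows with mixture complexity")
  } else {
    df <- object$by_ratio |>
      dplyr::group_by(.data$fraction) |>
      dplyr::summarise(mean = mean(.data$correlation),
                       sd = stats::sd(.data$correlation), .groups = "drop")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$mean)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                            ymax = .data$mean + .data$sd)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "fraction of first component",
                    y = "cross-concentration correlation",
                    title = "Mixture effects fade smoothly with ratio imbalance")
  }
}

#' Tidy an antennal lobe response
#'
#' @param x an `"al_response"`.
#' @param ... unused.
#' @return long tibble with `glomerulus`, `stimulus`, `population`,
#'   `rate_hz`.
#' @method tidy al_response
#' @export
tidy.al_response <- function(x, ...) {
  long <- function(mat, pop) {
    tibble::tibble(
      glomerulus = rep(seq_len(nrow(mat)), ncol(mat)),
      stimulus = rep(seq_len(ncol(mat)), each = nrow(mat)),
      population = pop,
      rate_hz = as.vector(mat)
    )
  }
  dplyr::bind_rows(long(x$orn, "ORN"), long(x$pn, "PN"), long(x$ln, "LN"))
}

#' @method autoplot al_response
#' @export
autoplot.al_response <- function(object, population = c("pn", "orn", "ln"), ...) {
  population <- match.arg(population)
  pop_up <- toupper(population)
  df <- tidy(object) |>
    dplyr::filter(.data$population == pop_up)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stimulus, y = .data$glomerulus,
                                   fill = .data$rate_hz)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "rate (Hz)") +
    ggplot2::labs(title = paste(toupper(population), "response pattern"),
                  x = "stimulus", y = "glomerulus")
}

#' Tidy an activation matrix
#'
#' @param x an `"activation_matrix"`.
#' @param ... unused.
#' @return long tibble with `receptor_id`, `odor_id`, `gmax`, `C_half`,
#'   `hill_n`.
#' @method tidy activation_matrix
#' @export
tidy.activation_matrix <- function(x, ...) {
  g <- x$gmax
  tibble::tibble(
    receptor_id = rep(rownames(g), ncol(g)),
    odor_id = rep(colnames(g), each = nrow(g)),
    gmax = as.vector(g),
    C_half = as.vector(x$C_half),
    hill_n = rep(x$hill_n, times = ncol(g))
  )
}

#' @method glance activation_matrix
#' @export
glance.activation_matrix <- function(x, ...) {
  tibble::as_tibble(x$achieved)
}

#' Plot average dose-response curves
#'
#' @param dose_response tibble from [run_dose_response()].
#' @return a ggplot.
#' @export
plot_dose_response <- function(dose_response) {
  ggplot2::ggplot(dose_response,
                  ggplot2::aes(x = .data$concentration, y = .data$rate_hz,
                               colour = factor(.data$n_components))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~.data$population, scales = "free_y") +
    ggplot2::labs(x = "component concentration", y = "mean rate (Hz)",
                  colour = "components")
}

#' Plot a receptor trajectory
#'
#' @param object a `"receptor_trajectory"` from [integrate_kinetics()].
#' @param ... unused.
#' @return a ggplot of the bound and activated fractions over time.
#' @method autoplot receptor_trajectory
#' @export
autoplot.receptor_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("r", "rstar"),
                            names_to = "state", values_to = "fraction")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$fraction,
                                   colour = .data$component,
                                   linetype = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "receptor fraction")
}
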