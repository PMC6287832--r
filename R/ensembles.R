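#' Distribution specifications for parameter ensembles
#'
#' Small helper describing how one kinetic parameter is drawn across the
#' population of odor-receptor combinations. Supported families:
#' * `uniform`: uniform on `(a, b)`.
#' * `exp_uniform`: uniform on the log scale between `a` and `b`
#'   (the exponential of a uniform variable; the printed range already gives
#'   the transformed endpoints).
#' * `log_uniform`: the natural log of a uniform variable on `(exp(a), exp(b))`
#'   (so the printed `(a, b)` are again the endpoints of the result).
#' * `normal`: Normal with mean `a`, sd `b`.
#' * `lognormal`: log-Normal with meanlog `a`, sdlog `b`.
#' * `constant`: always `a`.
#'
#' Hard bounds are enforced by resampling (up to `max_attempts` rounds), which
#' preserves the distribution's shape inside the bounds; a spec whose bounds
#' reject almost all draws is an error.
#'
#' @param family one of the names above.
#' @param a,b family parameters (min/max, or mean/sd).
#' @param lower,upper optional hard bounds (resample until satisfied).
#' @return an object of class `"dist_spec"`.
#' @examples
#' dist_spec("uniform", 0.5, 5)
#' dist_spec("normal", 0.3, 0.15, lower = 0)
#' @export
dist_spec <- function(family = c("uniform", "exp_uniform", "log_uniform",
                                 "normal", "lognormal", "constant"),
                      a, b = NULL, lower = -Inf, upper = Inf) {
  family <- match.arg(family)
  if (family != "constant" && is.null(b)) stop("`b` is required", call. = FALSE)
  if (family %in% c("uniform", "exp_uniform", "log_uniform") && a >= b) {
    stop("need a < b for range-based families", call. = FALSE)
  }
  if (family %in% c("normal", "lognormal") && b <= 0) {
    stop("sd must be > 0", call. = FALSE)
  }
  structure(list(family = family, a = a, b = if (is.null(b)) NA_real_ else b,
                 lower = lower, upper = upper),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec>", x$family, "(", x$a, ",", x$b, ")")
  if (is.finite(x$lower) || is.finite(x$upper)) {
    cat(" bounds [", x$lower, ",", x$upper, "]")
  }
  cat("\n")
  invisible(x)
}

#' Draw from a distribution specification
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @param max_attempts resampling rounds allowed before the hard bounds are
#'   declared infeasible.
#' @return numeric vector of length `n`, all within the hard bounds.
#' @export
sample_dist <- function(spec, n, max_attempts = 1e6) {
  stopifnot(inherits(spec, "dist_spec"))
  draw <- switch(spec$family,
    uniform = function(m) stats::runif(m, spec$a, spec$b),
    exp_uniform = function(m) exp(stats::runif(m, log(spec$a), log(spec$b))),
    log_uniform = function(m) log(stats::runif(m, exp(spec$a), exp(spec$b))),
    normal = function(m) stats::rnorm(m, spec$a, spec$b),
    lognormal = function(m) stats::rlnorm(m, spec$a, spec$b),
    constant = function(m) rep(spec$a, m)
  )
  x <- draw(n)
  bad <- x <= spec$lower | x >= spec$upper | !is.finite(x)
  if (n >= 100 && mean(bad) > 0.99) {
    stop("hard bounds reject > 99% of draws for family '", spec$family, "'",
         call. = FALSE)
  }
  attempts <- 0
  while (any(bad)) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      stop("hard bounds reject nearly all draws for family '", spec$family, "'",
           call. = FALSE)
    }
    x[bad] <- draw(sum(bad))
    bad <- x <= spec$lower | x >= spec$upper | !is.finite(x)
  }
  x
}

#' Ensemble specification for Monte-Carlo parameter studies
#'
#' Describes how a population of odor-receptor combinations is drawn per
#' trial: independent distributions for `k1^n`, `k_minus1` and the activation
#' equilibrium `K2 = k2/k_minus2`, plus the Hill-coefficient mode. In
#' `"fixed"` mode every receptor has `n = 0.65`; in `"variable"` mode each
#' receptor's Hill slope on the log10 axis is drawn log-normally
#' (`log n' ~ Normal(0.44, 0.22)`) and converted to the natural-exponent form
#' `n = n'/ln(10)` (median ~ 0.67). `k2` is drawn Normal(0.1, 0.01) (hard
#' lower bound 0) and `k_minus2 = k2/K2`.
#'
#' @param dist_k1n,dist_kminus1,dist_K2 [dist_spec()]s for `k1^n`, `k_minus1`
#'   and `K2`.
#' @param n_mode `"fixed"` or `"variable"`.
#' @param n_fixed Hill coefficient used in fixed mode.
#' @param pop_size receptors per trial (each receives two odor draws, paired
#'   into one binary mixture); must be >= 3 so correlations are defined.
#' @param dist_k2 spec for the activation rate `k2`.
#' @return an object of class `"ensemble_spec"`.
#' @examples
#' ensemble_spec_table1("uniform")
#' @export
ensemble_spec <- function(dist_k1n, dist_kminus1, dist_K2,
                          n_mode = c("fixed", "variable"), n_fixed = 0.65,
                          pop_size = 160,
                          dist_k2 = dist_spec("normal", 0.1, 0.01, lower = 0)) {
  n_mode <- match.arg(n_mode)
  stopifnot(inherits(dist_k1n, "dist_spec"), inherits(dist_kminus1, "dist_spec"),
            inherits(dist_K2, "dist_spec"))
  if (pop_size < 3) stop("pop_size must be >= 3", call. = FALSE)
  structure(list(dist_k1n = dist_k1n, dist_kminus1 = dist_kminus1,
                 dist_K2 = dist_K2, dist_k2 = dist_k2,
                 n_mode = n_mode, n_fixed = n_fixed, pop_size = pop_size),
            class = "ensemble_spec")
}

#' Ready-made ensemble specifications of the Monte-Carlo study
#'
#' The three biologically plausible parameter sets used in the correlation
#' study: `"uniform"` (`k1^n` in (0.5, 5), `k_minus1` in (0.005, 0.05), `K2`
#' in (0.01, 1)), `"exp_uniform"` (log-scale uniform over (0.63, 31.6),
#' (0.006, 0.1), (0.01, 1)) and `"normal"` (Normal(4, 1.5), Normal(0.03,
#' 0.01), Normal(0.3, 0.15), all with hard lower bound 0).
#'
#' @param family `"uniform"`, `"exp_uniform"` or `"normal"`.
#' @param n_mode,pop_size see [ensemble_spec()].
#' @return an `"ensemble_spec"`.
#' @export
ensemble_spec_table1 <- function(family = c("uniform", "exp_uniform", "normal"),
                                 n_mode = c("fixed", "variable"), pop_size = 160) {
  family <- match.arg(family)
  n_mode <- match.arg(n_mode)
  specs <- switch(family,
    uniform = list(
      dist_spec("uniform", 0.5, 5),
      dist_spec("uniform", 0.005, 0.05),
      dist_spec("uniform", 0.01, 1)
    ),
    exp_uniform = list(
      dist_spec("exp_uniform", 0.63, 31.6),
      dist_spec("exp_uniform", 0.006, 0.1),
      dist_spec("exp_uniform", 0.01, 1)
    ),
    normal = list(
      dist_spec("normal", 4, 1.5, lower = 0),
      dist_spec("normal", 0.03, 0.01, lower = 0),
      dist_spec("normal", 0.3, 0.15, lower = 0)
    )
  )
  ensemble_spec(specs[[1]], specs[[2]], specs[[3]], n_mode = n_mode,
                pop_size = pop_size)
}

#' Sample one ensemble trial
#'
#' Draws `pop_size` receptors, each with two independently sampled odors, so
#' that every receptor contributes two single odor-receptor combinations and
#' one binary mixture. `k1^n`, `k_minus1` and `K2` are drawn independently per
#' combination; `k1` is recovered as the drawn `k1^n` to the power `1/n`;
#' `k2` is drawn from its own spec and `k_minus2 = k2/K2`.
#'
#' @param spec an [ensemble_spec()].
#' @param n_odors odors drawn per receptor (2 for binary-mixture studies,
#'   3 when ternary mixtures are needed).
#' @return tibble of rate constants with columns `receptor_id`, `odor`
#'   (1..n_odors), the five rate constants, and the drawn `k1n` and `K2`.
#' @export
sample_ensemble <- function(spec, n_odors = 2) {
  stopifnot(inherits(spec, "ensemble_spec"))
  m <- spec$pop_size
  n <- if (spec$n_mode == "fixed") {
    rep(spec$n_fixed, m)
  } else {
    exp(stats::rnorm(m, 0.44, 0.22)) / log(10)
  }
  n2 <- rep(n, each = n_odors) # all odors of one receptor share n
  k1n <- sample_dist(spec$dist_k1n, n_odors * m)
  k_minus1 <- sample_dist(spec$dist_kminus1, n_odors * m)
  K2 <- sample_dist(spec$dist_K2, n_odors * m)
  k2 <- sample_dist(spec$dist_k2, n_odors * m)
  out <- tibble::tibble(
    receptor_id = rep(paste0("rec", seq_len(m)), each = n_odors),
    odor = rep(seq_len(n_odors), m),
    k1n = k1n, K2 = K2,
    k1 = k1n^(1 / n2),
    k_minus1 = k_minus1,
    k2 = k2,
    k_minus2 = k2 / K2,
    n = n2
  )
  if (stats::sd(out$k1n) == 0 || stats::sd(out$K2) == 0) {
    warning("degenerate ensemble: constant parameters make correlations undefined",
            call. = FALSE)
  }
  out
}
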