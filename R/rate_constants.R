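#' Construct a table of receptor kinetic parameters
#'
#' Builds a tibble of rate constants for the two-stage binding/activation
#' receptor model, one row per odor-receptor combination. The model describes
#' an odorant binding to a free receptor at rate `(k1 * c)^n` (with `c` the
#' dimensionless odorant concentration and `n` the Hill coefficient of
#' transduction), unbinding at rate `k_minus1`, and the bound receptor
#' activating/deactivating at rates `k2`/`k_minus2`. All rates are in 1/ms.
#'
#' @param k1 binding rate constant (ms^-1); enters the dynamics as `(k1*c)^n`.
#' @param k_minus1 unbinding rate constant (ms^-1).
#' @param k2 activation rate constant (ms^-1).
#' @param k_minus2 deactivation rate constant (ms^-1).
#' @param n Hill coefficient (> 0, dimensionless). Non-positive values are
#'   rejected: at `n = 0` the low-concentration response stays finite and for
#'   `n < 0` it diverges as `c -> 0`, neither of which is physical.
#' @param odor_id,receptor_id optional identifier columns.
#'
#' @return A tibble with columns `odor_id`, `receptor_id`, `k1`, `k_minus1`,
#'   `k2`, `k_minus2`, `n`.
#' @examples
#' rate_constants(k1 = 1.2, k_minus1 = 0.03, k2 = 0.1, k_minus2 = 0.2, n = 0.65)
#' @export
rate_constants <- function(k1, k_minus1, k2, k_minus2, n,
                           odor_id = NULL, receptor_id = NULL) {
  m <- max(length(k1), length(k_minus1), length(k2), length(k_minus2), length(n))
  out <- tibble::tibble(
    odor_id = if (is.null(odor_id)) paste0("odor", seq_len(m)) else rep_len(odor_id, m),
    receptor_id = if (is.null(receptor_id)) paste0("rec", seq_len(m)) else rep_len(receptor_id, m),
    k1 = rep_len(k1, m), k_minus1 = rep_len(k_minus1, m),
    k2 = rep_len(k2, m), k_minus2 = rep_len(k_minus2, m), n = rep_len(n, m)
  )
  validate_rate_constants(out)
  out
}

validate_rate_constants <- function(params) {
  needed <- c("k1", "k_minus1", "k2", "k_minus2", "n")
  missing <- setdiff(needed, names(params))
  if (length(missing)) {
    stop("rate-constant table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(params[needed])
  if (any(!is.finite(vals))) stop("rate constants must be finite", call. = FALSE)
  if (any(vals <= 0)) {
    stop("all rate constants and the Hill coefficient must be > 0", call. = FALSE)
  }
  invisible(params)
}

#' Derive steady-state constants from rate constants
#'
#' Adds the derived quantities that govern the receptor's dose-response curve:
#' `K1 = k1^n / k_minus1` and `K2 = k2 / k_minus2` (equilibrium constants of
#' binding and activation), `K2prime = K2 / (1 + K2)` (maximal activated
#' fraction, the high-concentration plateau), `Keff = K1 * K2` (the
#' low-concentration activation gain: `rstar ~ Keff * c^n` as `c -> 0`), and
#' `keff_rate = k1^n * k2` (the initial-slope constant controlling how fast
#' activation builds immediately after stimulus onset).
#'
#' @param params tibble of rate constants (see [rate_constants()]).
#' @return The input tibble with columns `K1`, `K2`, `K2prime`, `Keff`,
#'   `keff_rate` appended.
#' @examples
#' derive_constants(rate_constants(1.2, 0.03, 0.1, 0.2, 0.65))
#' @export
derive_constants <- function(params) {
  validate_rate_constants(params)
  dplyr::mutate(params,
    K1 = .data$k1^.data$n / .data$k_minus1,
    K2 = .data$k2 / .data$k_minus2,
    K2prime = .data$K2 / (1 + .data$K2),
    Keff = .data$K1 * .data$K2,
    keff_rate = .data$k1^.data$n * .data$k2
  )
}

#' Read or write rate-constant tables as CSV
#'
#' The on-disk format has header
#' `odor_id,receptor_id,k1,k_minus1,k2,k_minus2,n`.
#'
#' @param path file path.
#' @param params tibble of rate constants.
#' @return `read_rate_constants()` returns a validated tibble;
#'   `write_rate_constants()` returns `params` invisibly.
#' @export
read_rate_constants <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_rate_constants(out)
  out
}

#' @rdname read_rate_constants
#' @export
write_rate_constants <- function(params, path) {
  validate_rate_constants(params)
  cols <- c("odor_id", "receptor_id", "k1", "k_minus1", "k2", "k_minus2", "n")
  utils::write.csv(params[intersect(cols, names(params))], path, row.names = FALSE)
  invisible(params)
}
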