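#' Normalized Euclidean distance between response patterns
#'
#' `d = sqrt(mean((x - y)^2))`: the root-mean-square difference across
#' receptor types, the similarity measure used to compare odor response
#' patterns.
#'
#' @param x,y numeric vectors of equal length (>= 1).
#' @return scalar distance.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5 / sqrt(2)
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1) {
    stop("x and y must have equal length >= 1", call. = FALSE)
  }
  sqrt(mean((x - y)^2))
}

#' All pairwise normalized Euclidean distances between odor columns
#'
#' @param mat receptors x odors matrix.
#' @return odors x odors symmetric matrix of [euclidean_distance()]s.
#' @export
pattern_distances <- function(mat) {
  as.matrix(stats::dist(t(mat))) / sqrt(nrow(mat))
}

#' Default target statistics for the activation-pattern generator
#'
#' Loads the target statistics shipped with the package
#' (`inst/extdata/default_target_stats.json`): per-receptor means and
#' standard deviations of the saturating activation `gmax` across odors, a
#' sample of pairwise odor-odor pattern correlations, and a 16 x 16 target
#' matrix of normalized Euclidean distances between odor patterns. These are
#' synthetic reference statistics chosen to emulate the published summary
#' properties of honey-bee glomerular calcium-imaging responses
#' (heterogeneous per-glomerulus response amplitudes, mostly positive
#' odor-odor correlations, graded odor similarity structure); they are not
#' measured data.
#'
#' @return list with elements `receptor_mean`, `receptor_sd`, `corr_sample`,
#'   `dist_target`.
#' @export
default_target_stats <- function() {
  path <- system.file("extdata", "default_target_stats.json", package = "olfmix")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    receptor_mean = as.numeric(raw$receptor_mean),
    receptor_sd = as.numeric(raw$receptor_sd),
    corr_sample = as.numeric(raw$corr_sample),
    dist_target = matrix(as.numeric(raw$dist_target), nrow = raw$n_odors)
  )
}

ks_distance <- function(x, y) {
  # max absolute difference of the two empirical CDFs
  grid <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(grid)
  fy <- stats::ecdf(y)(grid)
  max(abs(fx - fy))
}

#' Generate a synthetic glomerular activation matrix
#'
#' Builds a receptors x odors matrix of saturating activations `gmax` in
#' (0, 1) whose summary statistics match user-supplied targets: per-receptor
#' mean and standard deviation across odors (within `stat_tol`), the
#' distribution of pairwise odor-odor pattern correlations (Kolmogorov-
#' Smirnov distance below `ks_tol`), and the matrix of pairwise normalized
#' Euclidean distances between odor patterns (relative RMS error below
#' `dist_tol`). Patterns start as correlated Gaussian draws (columns given the
#' target correlation structure, rows rescaled to the target moments) and the
#' distance matrix is then matched by damped gradient descent with the row
#' moments re-imposed after every sweep.
#'
#' @param n_receptors,n_odors matrix dimensions; defaults follow the
#'   160-glomerulus, 16-odor setting. Targets are recycled/truncated to these
#'   sizes.
#' @param target_stats list as returned by [default_target_stats()].
#' @param seed integer seed; runs are reproducible for a fixed seed.
#' @param max_iter gradient sweeps for the distance matching.
#' @param stat_tol,ks_tol,dist_tol acceptance tolerances (relative, KS, and
#'   relative RMS respectively).
#' @param hill_bounds_C,hill_bounds_nprime hard bounds for the sampled Hill
#'   descriptors attached to each combination: half-activation point
#'   `C_half ~ Normal(-3, 1)` truncated to (-4.4, -0.4) and log10-axis slope
#'   `n' ~ logNormal(0.45, 0.3)` truncated to (0.7, 3.5); the kinetic Hill
#'   coefficient is `n = n'/ln(10)`, shared by all odors of one receptor.
#' @return an object of class `"activation_matrix"`: list with `gmax`
#'   (matrix), `C_half` (matrix), `hill_n` (per-receptor vector), `achieved`
#'   (diagnostics) and `seed`.
#' @export
generate_activation_matrix <- function(n_receptors = 160, n_odors = 16,
                                       target_stats = default_target_stats(),
                                       seed = 1, max_iter = 400,
                                       stat_tol = 0.05, ks_tol = 0.1,
                                       dist_tol = 0.05,
                                       hill_bounds_C = c(-4.4, -0.4),
                                       hill_bounds_nprime = c(0.7, 3.5)) {
  set.seed(seed)
  mu <- rep_len(target_stats$receptor_mean, n_receptors)
  sg <- rep_len(target_stats$receptor_sd, n_receptors)
  D_t <- target_stats$dist_target
  if (nrow(D_t) > n_odors) {
    # smaller odor panels use the leading block of the target
    D_t <- D_t[seq_len(n_odors), seq_len(n_odors)]
  } else if (nrow(D_t) < n_odors) {
    stop("target distance matrix must be at least ", n_odors, " x ", n_odors,
         call. = FALSE)
  }
  corr_sample <- target_stats$corr_sample

  # start: columns with the target correlation structure implied by corr_sample
  n_pairs <- n_odors * (n_odors - 1) / 2
  rho <- sample(corr_sample, n_pairs, replace = length(corr_sample) < n_pairs)
  C <- diag(n_odors)
  C[upper.tri(C)] <- rho
  C <- C + t(C) - diag(n_odors)
  ev <- eigen(C, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 1e-6))) %*% t(ev$vectors)
  X <- matrix(stats::rnorm(n_receptors * n_odors), n_receptors) %*% L

  renorm <- function(X) {
    # re-impose per-receptor moments, then keep values inside (0, 1)
    rs <- apply(X, 1, stats::sd)
    rs[rs == 0] <- 1
    X <- (X - rowMeans(X)) / rs * sg + mu
    pmin(pmax(X, 1e-3), 1 - 1e-3)
  }
  X <- renorm(X)

  # damped gradient descent on the distance-matrix mismatch, with the row
  # moments re-imposed after every sweep; the step shrinks when a sweep fails
  # to improve and the best iterate is kept
  N <- n_receptors
  step <- 0.4
  rel_err <- function(X) {
    D <- pattern_distances(X)
    sqrt(mean((D - D_t)[upper.tri(D)]^2)) / mean(D_t[upper.tri(D_t)])
  }
  best_X <- X
  best_err <- rel_err(X)
  for (it in seq_len(max_iter)) {
    if (best_err < dist_tol * 0.6) break
    D <- pattern_distances(X)
    G <- matrix(0, N, n_odors)
    for (j in seq_len(n_odors)) {
      diff <- X[, j] - X
      dj <- D[j, ]
      dj[j] <- 1
      coef <- (dj - D_t[j, ]) / (N * dj)
      coef[j] <- 0
      G[, j] <- diff %*% coef
    }
    X <- renorm(X - 2 * step * G)
    err <- rel_err(X)
    if (err < best_err) {
      best_err <- err
      best_X <- X
    } else {
      step <- max(step * 0.7, 0.02)
      X <- best_X
    }
  }
  X <- best_X
  D <- pattern_distances(X)
  achieved <- list(
    mean_rel_err = max(abs(rowMeans(X) - mu) / mu),
    sd_rel_err = max(abs(apply(X, 1, stats::sd) - sg) / sg),
    corr_ks = ks_distance(stats::cor(X)[upper.tri(D)], corr_sample),
    dist_rms_rel = sqrt(mean((D - D_t)[upper.tri(D)]^2)) / mean(D_t[upper.tri(D_t)]),
    iterations = it
  )
  if (achieved$dist_rms_rel > dist_tol) {
    stop(sprintf(paste0("distance matching failed: achieved relative RMS %.3f ",
                        "> tolerance %.3f after %d iterations"),
                 achieved$dist_rms_rel, dist_tol, max_iter), call. = FALSE)
  }

  truncnorm <- function(m, mean, sd, lo, hi) {
    x <- stats::rnorm(m, mean, sd)
    while (any(bad <- x <= lo | x >= hi)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  # n' log-normal with the hard bounds applied to n' itself
  nprime <- exp(truncnorm(n_receptors, 0.45, 0.3,
                          log(hill_bounds_nprime[1]), log(hill_bounds_nprime[2])))
  C_half <- matrix(truncnorm(n_receptors * n_odors, -3, 1,
                             hill_bounds_C[1], hill_bounds_C[2]),
                   n_receptors, n_odors)
  dimnames(X) <- list(paste0("rec", seq_len(n_receptors)),
                      paste0("odor", seq_len(n_odors)))
  structure(
    list(gmax = X, C_half = C_half, hill_n = nprime / log(10),
         achieved = achieved, seed = seed),
    class = "activation_matrix"
  )
}

#' @export
print.activation_matrix <- function(x, ...) {
  cat("<activation_matrix> ", nrow(x$gmax), " receptors x ", ncol(x$gmax),
      " odors\n", sep = "")
  a <- x$achieved
  cat(sprintf("  matched: mean %.1f%%, sd %.1f%%, corr KS %.3f, dist RMS %.1f%% (%d iter)\n",
              100 * a$mean_rel_err, 100 * a$sd_rel_err, a$corr_ks,
              100 * a$dist_rms_rel, a$iterations))
  invisible(x)
}

#' Convert an activation matrix to a per-combination kinetic parameter table
#'
#' Every odor-receptor combination is calibrated with [calibrate_from_hill()]
#' from its `gmax`, `C_half` and the receptor's Hill coefficient.
#'
#' @param activation an `"activation_matrix"`.
#' @param k_minus1,k2 kinetic timescale parameters passed to
#'   [calibrate_from_hill()].
#' @return tibble of rate constants with `odor_id` and `receptor_id` columns.
#' @export
activation_to_params <- function(activation, k_minus1 = 0.03, k2 = 0.1) {
  stopifnot(inherits(activation, "activation_matrix"))
  g <- activation$gmax
  nr <- nrow(g); no <- ncol(g)
  suppressWarnings(calibrate_from_hill(
    gmax = as.vector(g),
    C_half = as.vector(activation$C_half),
    n = rep(activation$hill_n, times = no),
    k_minus1 = k_minus1, k2 = k2,
    odor_id = rep(colnames(g), each = nr),
    receptor_id = rep(rownames(g), times = no)
  ))
}

#' Write / read an activation matrix (CSV + JSON sidecar)
#'
#' The `gmax` matrix is stored as CSV (receptors x odors); the Hill
#' descriptors and generator diagnostics go to `<path>.json`.
#'
#' @param activation an `"activation_matrix"`.
#' @param path CSV path.
#' @return `write_activation_matrix()` the input, invisibly;
#'   `read_activation_matrix()` an `"activation_matrix"`.
#' @export
write_activation_matrix <- function(activation, path) {
  utils::write.csv(as.data.frame(activation$gmax), path, row.names = TRUE)
  side <- list(C_half = activation$C_half, hill_n = activation$hill_n,
               achieved = activation$achieved, seed = activation$seed)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(activation)
}

#' @rdname write_activation_matrix
#' @export
read_activation_matrix <- function(path) {
  g <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(gmax = g,
         C_half = matrix(as.numeric(side$C_half), nrow(g), ncol(g)),
         hill_n = as.numeric(side$hill_n),
         achieved = side$achieved, seed = side$seed),
    class = "activation_matrix"
  )
}
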