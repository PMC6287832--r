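# random rate-constant tables spanning realistic orders of magnitude
random_params <- function(m, n = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- runif(1, 0.4, 1.6)
  rate_constants(
    k1 = exp(runif(m, log(0.05), log(20))),
    k_minus1 = exp(runif(m, log(0.005), log(0.5))),
    k2 = exp(runif(m, log(0.02), log(0.5))),
    k_minus2 = exp(runif(m, log(0.05), log(1))),
    n = n
  )
}

# build a table with prescribed (K2prime, Keff) pairs and shared n
params_from_constants <- function(K2prime, Keff, n = 1, k_minus1 = 0.05, k2 = 0.1) {
  K2 <- K2prime / (1 - K2prime)
  K1 <- Keff / K2
  rate_constants(
    k1 = (K1 * k_minus1)^(1 / n),
    k_minus1 = k_minus1,
    k2 = k2,
    k_minus2 = k2 / K2,
    n = n
  )
}

# self-consistent target statistics at reduced size: summary stats of a small
# latent-factor reference matrix (the shipped defaults are for 160 x 16)
make_target_stats <- function(n_rec, n_odor, seed = 1) {
  set.seed(seed)
  k <- 3
  loadings <- matrix(runif(n_odor * k), n_odor)
  loadings <- loadings / rowSums(loadings)
  X <- matrix(rnorm(n_rec * k), n_rec) %*% t(loadings) +
    0.6 * matrix(rnorm(n_rec * n_odor), n_rec)
  G <- stats::plogis(runif(n_rec, -0.8, 0.2) + runif(n_rec, 0.5, 1.5) * X)
  list(
    receptor_mean = rowMeans(G),
    receptor_sd = apply(G, 1, sd),
    corr_sample = cor(G)[upper.tri(diag(n_odor))],
    dist_target = as.matrix(dist(t(G))) / sqrt(n_rec)
  )
}

small_activation_matrix <- function(n_rec, n_odor, seed = 1) {
  generate_activation_matrix(
    n_receptors = n_rec, n_odors = n_odor, seed = seed,
    target_stats = make_target_stats(n_rec, n_odor, seed = seed)
  )
}
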