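# Builds inst/extdata/default_target_stats.json: synthetic target statistics
# for the activation-pattern generator. A reference receptors-x-odors matrix
# is produced from a simple latent-factor model (shared odor factors plus
# receptor noise, heterogeneous per-receptor amplitude), and its summary
# statistics -- per-receptor mean/sd of gmax, pairwise odor-odor pattern
# correlations, and the normalized Euclidean distance matrix -- become the
# shipped defaults. Run from the package root; deterministic.
set.seed(20181210)

n_rec <- 160
n_odor <- 16

# three latent odor "chemical classes" drive correlated tuning
n_fac <- 3
loadings <- matrix(runif(n_odor * n_fac), n_odor)
loadings <- loadings / rowSums(loadings)
fac <- matrix(rnorm(n_rec * n_fac), n_rec)
X <- fac %*% t(loadings) + 0.6 * matrix(rnorm(n_rec * n_odor), n_rec)

# heterogeneous receptor amplitudes, squashed into (0, 1)
amp <- runif(n_rec, 0.5, 1.5)
base <- runif(n_rec, -0.8, 0.2)
G <- stats::plogis(base + amp * X)

stats_out <- list(
  n_receptors = n_rec,
  n_odors = n_odor,
  receptor_mean = rowMeans(G),
  receptor_sd = apply(G, 1, sd),
  corr_sample = cor(G)[upper.tri(diag(n_odor))],
  dist_target = as.vector(as.matrix(dist(t(G))) / sqrt(n_rec))
)
jsonlite::write_json(stats_out, "inst/extdata/default_target_stats.json",
                     digits = 8, auto_unbox = TRUE, pretty = TRUE)
cat("wrote", file.path("inst/extdata", "default_target_stats.json"), "\n")
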