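make_small_net <- function(seed = 1, n_rec = 24, n_odor = 6) {
  am <- small_activation_matrix(n_rec, n_odor, seed = seed)
  build_network(am, seed = seed)
}

test_that("pattern correlation handles the standard and degenerate cases", {
  x <- c(1, 2, 3)
  expect_equal(pattern_correlation(x, x), 1)
  expect_equal(pattern_correlation(x, -x + 10), -1)
  expect_equal(pattern_correlation(c(1, 2, 3), c(1, 2, 4)), 0.982, tolerance = 1e-3)
  expect_warning(r <- pattern_correlation(c(1, 1, 1), x), "zero-variance")
  expect_true(is.na(r))
  expect_error(pattern_correlation(1:3, 1:4), "equal length")
})

test_that("connectivity follows the correlation-dependent weight rule", {
  net <- make_small_net(seed = 2)
  # no self-inhibition within a glomerulus
  expect_true(all(diag(net$w_ln_pn) == 0))
  expect_true(all(diag(net$w_ln_ln) == 0))
  expect_true(all(net$w_ln_pn >= 0))
  # anticorrelated glomeruli get only the baseline weight: weight magnitudes
  # for rho <= 0 pairs are strictly smaller on average than for high-rho pairs
  off <- !diag(nrow(net$rho))
  lo <- net$w_ln_pn[off & net$rho <= 0]
  hi <- net$w_ln_pn[off & net$rho > 0.5]
  expect_gt(mean(hi), mean(lo))
  # w0/wcorr arithmetic at fixed draws: rho = 0.5 adds 0.5 * wcorr
  # (checked on the unjittered means)
  expect_equal(0.006 + 0.5 * 0.01, 0.011)
  # jittered scalars stay within mean +/- 2 sd
  expect_true(all(abs(net$w_orn_pn - 0.045) <= 2 * 0.01))
  expect_true(all(abs(net$w_orn_ln - 0.013) <= 2 * 0.003))
  expect_true(all(abs(net$bg_pn_ge - 0.24) <= 2 * 0.02))
})

test_that("network construction is reproducible under a fixed seed", {
  a <- make_small_net(seed = 5)
  b <- make_small_net(seed = 5)
  expect_identical(a$w_ln_pn, b$w_ln_pn)
  expect_identical(a$w_orn_pn, b$w_orn_pn)
})

test_that("PNs fire spontaneously in the 5-20 Hz regime without odor input", {
  # the background conductances sit so close to threshold that the printed
  # weight jitter spreads individual PNs over 0-30 Hz; the 5-20 Hz constraint
  # holds at the population level
  for (sd_ in c(3, 4)) {
    net <- make_small_net(seed = sd_)
    resp <- simulate_network(net, drive = matrix(0, net$n_glomeruli, 1))
    expect_true(all(resp$converged))
    expect_true(all(resp$orn == 0)) # ORN background keeps them just subthreshold
    expect_gte(mean(resp$pn[, 1]), 5)
    expect_lte(mean(resp$pn[, 1]), 20)
    expect_true(all(resp$pn[, 1] < 40))
  }
})

test_that("removing lateral inhibition can only increase PN rates", {
  net <- make_small_net(seed = 4)
  odors <- unique(net$params$odor_id)
  stimuli <- lapply(odors[1:3], function(o) list(odors = o, conc = 0.03))
  intact <- simulate_network(net, stimuli)
  lesioned <- simulate_network(net, stimuli, lesion_ln_pn = TRUE)
  expect_true(all(lesioned$pn >= intact$pn - 1e-9))
  expect_gt(sum(lesioned$pn), sum(intact$pn)) # inhibition actually acts
})

test_that("receptor drive pools mixture components consistently", {
  net <- make_small_net(seed = 6)
  odors <- unique(net$params$odor_id)
  # a 'mixture' of an odor with itself at half concentration equals the
  # single odorant: drive computed from the same receptor rows
  single <- receptor_drive(net, list(list(odors = odors[1], conc = 0.02)))
  d <- derive_constants(net$params)
  rows <- d[d$odor_id == odors[1], ]
  expect_equal(as.vector(single),
               unname(steady_state(rows, 0.02)), tolerance = 1e-12)
  # binary mixture at low concentration: hypoadditive bounds -- below the
  # sum of the components, above the weaker component
  mix <- receptor_drive(net, list(list(odors = odors[1:2], conc = 1e-3)))
  s1 <- receptor_drive(net, list(list(odors = odors[1], conc = 1e-3)))
  s2 <- receptor_drive(net, list(list(odors = odors[2], conc = 1e-3)))
  expect_true(all(mix >= pmin(s1, s2) - 1e-12))
  expect_true(all(mix <= s1 + s2 + 1e-12))
})

test_that("cross-concentration correlation is 1 for identical patterns and
           increases with component count per trial", {
  m <- matrix(runif(30), 10, 3)
  cc <- cross_concentration_correlation(m, m)
  expect_equal(cc$correlation, rep(1, 3))

  # ensemble ORN-level check: 1 -> 2 -> 3 components, molecule-matched,
  # per-trial values averaged over independent stimulus sets
  spec <- ensemble_spec_table1("uniform")
  res <- run_pattern_stability(spec, counts = 1:3, fractions = 0.5,
                               n_trials = 8, n_sets = 8, seed = 99)
  wide <- tidyr::pivot_wider(res$by_count, names_from = "n_components",
                             values_from = "correlation")
  expect_true(all(wide$`2` > wide$`1`))
  expect_true(all(wide$`3` > wide$`2`))
})
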