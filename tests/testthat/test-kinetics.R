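test_that("w(n) reduces correctly in its limiting cases", {
  # single component and n = 1 are exactly neutral
  expect_equal(w_factor(2.3, 0.7, 0.65), 1)
  expect_equal(w_factor(c(1.1, 3, 0.4), c(0.2, 0.5, 1), 1), 1)
  # equal binding terms: N identical components give N^(n-1)
  expect_equal(w_factor(c(1, 1), c(0.5, 0.5), 0.5), 2^(-0.5))
  expect_equal(w_factor(c(2, 2, 2), c(1, 1, 1), 0.65), 3^(0.65 - 1))
  # all-zero concentration falls back to 1 by convention
  expect_message(w <- w_factor(c(1, 2), c(0, 0), 0.65), "zero")
  expect_equal(w, 1)
  expect_error(w_factor(c(1, 2), c(0.1, 0.1), -1), "positive")
})

test_that("single-odorant steady state matches the closed form and its limits", {
  p <- params_from_constants(K2prime = 0.29, Keff = 8.33, n = 1)
  # at ceff = 1: r* = 1/(1/0.29 + 1/8.33)
  expect_equal(steady_state(p, 1), 1 / (1 / 0.29 + 1 / 8.33), tolerance = 1e-10)
  expect_equal(steady_state(p, 1), 0.2802, tolerance = 1e-3)
  expect_equal(steady_state(p, 0), 0)
  expect_error(steady_state(p, -0.1), ">= 0")

  # monotone increasing, bounded by K2prime, linear gain Keff at low c
  ps <- random_params(20, seed = 42)
  d <- derive_constants(ps)
  cgrid <- 10^seq(-6, 4, by = 0.5)
  for (i in seq_len(nrow(ps))) {
    r <- steady_state(ps[i, ], cgrid)
    expect_true(all(diff(r) > 0))
    expect_true(all(r < d$K2prime[i]))
  }
  # c -> infinity approaches the plateau; symmetric activation gives 1/2
  p_sym <- rate_constants(2, 0.05, 0.1, 0.1, 0.8)
  expect_equal(steady_state(p_sym, 1e8), 0.5, tolerance = 1e-4)
  # c -> 0: r*/c^n -> Keff (checked where Keff*c^n < 1e-3 * K2prime)
  for (i in seq_len(nrow(ps))) {
    c0 <- (1e-3 * d$K2prime[i] / d$Keff[i])^(1 / d$n[i])
    expect_equal(steady_state(ps[i, ], c0) / c0^d$n[i], d$Keff[i],
                 tolerance = 1e-2)
  }
})

test_that("mixture constants reproduce hand-computed weights and bounds", {
  p <- params_from_constants(K2prime = c(0.29, 0.5), Keff = c(8.33, 20), n = 1)
  mc <- mixture_constants(p)
  expect_equal(mc$p[[1]], c(0.294, 0.706), tolerance = 1e-3)
  expect_equal(mc$K2mixprime, 1 / (0.294 / 0.29 + 0.706 / 0.5), tolerance = 1e-3)
  expect_equal(mc$K2mixprime, 0.412, tolerance = 1e-3)

  # single component: identity
  mc1 <- mixture_constants(p[1, ])
  d1 <- derive_constants(p[1, ])
  expect_equal(mc1$Keffmix, d1$Keff)
  expect_equal(mc1$K2mixprime, d1$K2prime)

  # two identical components: doubled-concentration single odorant
  p_self <- params_from_constants(K2prime = c(0.3, 0.3), Keff = c(5, 5), n = 0.65)
  mcs <- mixture_constants(p_self)
  expect_equal(mcs$Keffmix, 2^0.65 * 5, tolerance = 1e-10)
  expect_equal(mcs$K2mixprime, 0.3, tolerance = 1e-10)

  # harmonic-mean plateau lies strictly between differing component plateaus
  set.seed(3)
  for (i in 1:50) {
    K2p <- runif(2, 0.05, 0.9)
    Keff <- runif(2, 0.5, 50)
    pm <- params_from_constants(K2p, Keff, n = 0.65)
    mcb <- mixture_constants(pm)
    expect_gt(mcb$K2mixprime, min(K2p))
    expect_lt(mcb$K2mixprime, max(K2p))
  }
  expect_error(
    mixture_constants(rate_constants(c(1, 1), 0.05, 0.1, 0.2, n = c(0.5, 1))),
    "share the Hill coefficient"
  )
})

test_that("mixture steady state agrees with the effective-constant closed form", {
  set.seed(11)
  for (i in 1:30) {
    m <- sample(2:4, 1)
    p <- random_params(m)
    cc <- 10^runif(1, -4, 1)
    mc <- mixture_constants(p, cc)
    direct <- steady_state_mixture(p, cc)$rstar_total
    closed <- 1 / (1 / mc$K2mixprime + 1 / (mc$Keffmix * cc^mc$n))
    expect_equal(direct, closed, tolerance = 1e-12)
  }
  # all-zero concentration: nothing binds
  p <- random_params(2, seed = 5)
  expect_equal(steady_state_mixture(p, 0)$rstar_total, 0)
})

test_that("high-concentration mixture limit is the weighted harmonic mean", {
  p <- params_from_constants(K2prime = c(0.29, 0.5), Keff = c(8.33, 20), n = 1)
  lim <- steady_state_mixture(p, 1e8)$rstar_total
  expect_equal(lim, 0.412, tolerance = 1e-3)
  expect_gt(lim, 0.29)
  expect_lt(lim, 0.5)
})

test_that("low-concentration interaction sign follows the Hill coefficient", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(c(runif(1, 0.3, 0.95), 1, runif(1, 1.05, 2)), 1)
    p <- random_params(2, n = n)
    d <- derive_constants(p)
    # deep low-concentration regime: even the depletion terms are < 1e-5,
    # so second-order competition effects are below 1e-9 absolute
    c0 <- min((1e-5 / (d$K1 * (1 + d$K2)))^(1 / n))
    mix <- steady_state_mixture(p, c0)$rstar_total
    singles <- steady_state(p, c0)
    if (n < 1) {
      # hypoadditive: below the sum, above the weakest component
      expect_lt(mix, sum(singles))
      expect_gt(mix, min(singles))
    } else if (n == 1) {
      expect_lt(abs(mix - sum(singles)), 1e-9)
    } else {
      expect_gt(mix, sum(singles))
    }
  }
})

test_that("interaction classification matches the analytic regimes", {
  expect_equal(classify_interaction(c(1.5, 1, 0.65), "low_c"),
               c("synergistic", "additive", "hypoadditive"))
  expect_equal(classify_interaction(c(0.65, 1.5), "high_c"),
               c("hypoadditive", "hypoadditive"))
  expect_error(classify_interaction(0, "low_c"), "> 0")
  expect_error(classify_interaction(-1, "high_c"), "> 0")
})

test_that("short-time activation follows the quadratic ramp", {
  p <- rate_constants(1, 0.001, 0.1, 0.2, n = 1)
  expect_equal(initial_activation(p, conc = 0.01, t = 1), 5e-4)
  expect_equal(initial_activation(p, conc = 0.01, t = 0), 0)
  # mixture version carries w(n) and the summed slope constants
  pm <- random_params(2, n = 0.65, seed = 9)
  d <- derive_constants(pm)
  w <- w_factor(pm$k1, c(0.01, 0.01), 0.65)
  expect_equal(initial_activation(pm, 0.01, 0.5),
               w * sum(d$keff_rate * 0.01^0.65) * 0.25 / 2, tolerance = 1e-12)
})

test_that("nested binary reduction reproduces the direct N-component steady state", {
  set.seed(33)
  for (i in 1:100) {
    m <- sample(3:5, 1)
    p <- random_params(m)
    cc <- 10^runif(1, -4, 1)
    expect_equal(nested_steady_state(reduce_mixture(p), cc),
                 steady_state_mixture(p, cc)$rstar_total, tolerance = 1e-10)
  }
  # N = 2: the representation is the mixture's own effective constants
  p2 <- random_params(2, seed = 14)
  red <- reduce_mixture(p2)
  d2 <- derive_constants(p2)
  expect_null(red$inner_reduction)
  expect_equal(red$inner$Keff_prime, d2$Keff[1])
  expect_equal(red$inner$K2_doubleprime, d2$K2prime[1])
  mc <- mixture_constants(p2, 0.05)
  expect_equal(nested_steady_state(red, 0.05),
               1 / (1 / mc$K2mixprime + 1 / (mc$Keffmix * 0.05^mc$n)),
               tolerance = 1e-12)
})

test_that("molecule-matched mixtures have the larger pooled initial gain (n < 1)", {
  # at matched molecule count, the N-component initial activation
  # w * sum(keff_i) * c^n exceeds the average single-odorant activation
  # mean(keff_i) * (N c)^n because w(n) >= N^(n-1) for n <= 1
  set.seed(44)
  for (i in 1:50) {
    m <- sample(2:4, 1)
    p <- random_params(m, n = runif(1, 0.3, 1))
    d <- derive_constants(p)
    cc <- 1e-3
    w <- w_factor(d$k1, rep(cc, m), d$n[1])
    expect_gte(w, m^(d$n[1] - 1) - 1e-12)
    mix_gain <- initial_activation(p, cc, t = 0.5)
    avg_single <- mean(vapply(seq_len(m), function(j) {
      initial_activation(p[j, ], m * cc, t = 0.5)
    }, numeric(1)))
    expect_gte(mix_gain, avg_single - 1e-15)
  }
})
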