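test_that("the correlation study is deterministic given a seed", {
  spec <- ensemble_spec_table1("uniform", pop_size = 40)
  a <- run_table1(spec, n_trials = 10, seed = 42)
  b <- run_table1(spec, n_trials = 10, seed = 42)
  expect_identical(a$differences, b$differences)
  c2 <- run_table1(spec, n_trials = 10, seed = 43)
  expect_false(identical(a$differences, c2$differences))
})

test_that("self-mixtures give a vanishing correlation difference", {
  # if both 'odors' of every receptor are identical, the mixture constants
  # collapse onto the single-odorant constants and the difference is ~0
  spec <- ensemble_spec_table1("uniform", pop_size = 100)
  set.seed(1)
  diffs <- replicate(20, {
    d <- derive_constants(sample_ensemble(spec))
    iA <- seq(1, nrow(d), by = 2)
    d[iA + 1, ] <- d[iA, ] # duplicate odor A as odor B
    n <- d$n[iA]
    w <- (d$k1[iA] + d$k1[iA + 1])^n / (d$k1[iA]^n + d$k1[iA + 1]^n)
    Keffmix <- w * (d$Keff[iA] + d$Keff[iA + 1])
    K2mixprime <- 1 / (0.5 / d$K2prime[iA] + 0.5 / d$K2prime[iA + 1])
    cor(Keffmix, K2mixprime) - cor(d$Keff[iA], d$K2prime[iA])
  })
  expect_lt(max(abs(diffs)), 1e-12)
})

test_that("n = 1 with identical binding rates degenerates gracefully", {
  spec <- ensemble_spec(
    dist_spec("constant", 2), dist_spec("uniform", 0.005, 0.05),
    dist_spec("uniform", 0.01, 1), n_fixed = 1, pop_size = 80
  )
  res <- suppressWarnings(run_table1(spec, n_trials = 5, seed = 2))
  expect_true(all(is.finite(res$differences)))
  # w = 1 here, so Keffmix is the plain sum of the component gains
  d <- derive_constants(suppressWarnings(sample_ensemble(spec)))
  w <- w_factor(d$k1[1:2], c(1, 1), 1)
  expect_equal(w, 1)
})

test_that("tidy and glance summarise correlation studies", {
  res <- run_table1(ensemble_spec_table1("uniform", pop_size = 40),
                    n_trials = 8, seed = 3)
  td <- tidy(res)
  expect_equal(nrow(td), 8)
  expect_named(td, c("trial", "corr_difference", "discordant"))
  gl <- glance(res)
  expect_equal(gl$mean_corr_difference, mean(td$corr_difference))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("ORN-rate level reports a larger mixture advantage than constants level", {
  spec <- ensemble_spec_table1("uniform")
  rc <- run_table1(spec, "constants", n_trials = 30, seed = 4)
  rr <- run_table1(spec, "orn_rate", n_trials = 30, seed = 4)
  expect_gt(rr$mean_corr_difference, rc$mean_corr_difference)
  expect_gt(rc$mean_corr_difference, 0)
})

test_that("dose-response averages obey the mixture inequalities", {
  am <- small_activation_matrix(36, 8, seed = 11)
  net <- build_network(am, seed = 11)
  dr <- run_dose_response(net, conc = c(1e-9, 1e-4, 3e-1), n_components = 1:3,
                          n_sets = 6, seed = 11)
  orn <- tidyr::pivot_wider(dr[dr$population == "ORN", ],
                            names_from = "n_components", values_from = "rate_hz")
  lo <- orn[orn$concentration == 1e-4, ]
  hi <- orn[orn$concentration == 3e-1, ]
  # low concentration: 1 < mixture/single < N
  expect_gt(lo$`2`, lo$`1`)
  expect_lt(lo$`2`, 2 * lo$`1`)
  expect_gt(lo$`3`, lo$`1`)
  expect_lt(lo$`3`, 3 * lo$`1`)
  # high concentration: near-identical averages
  expect_lt(abs(hi$`2` - hi$`1`) / hi$`1`, 0.15)
  expect_lt(abs(hi$`3` - hi$`1`) / hi$`1`, 0.15)
  # at vanishing stimulus both populations return to the spontaneous regime
  # (a clamped-k1 receptor can stay hypersensitive, so bound the mean)
  orn0 <- dr[dr$population == "ORN" & dr$concentration == 1e-9, ]
  expect_true(all(orn0$rate_hz < 5))
  pn0 <- dr[dr$population == "PN" & dr$concentration == 1e-9, ]
  expect_true(all(pn0$rate_hz > 5 & pn0$rate_hz < 20))
})

test_that("mixture effects fade smoothly with ratio imbalance, in both models", {
  spec <- ensemble_spec_table1("uniform")
  for (model in c("consistent", "legacy")) {
    res <- run_pattern_stability(spec, counts = 1:2,
                                 fractions = c(0.5, 0.75, 0.9, 1),
                                 n_trials = 12, seed = 7, model = model)
    ratio <- res$by_ratio |>
      dplyr::group_by(.data$fraction) |>
      dplyr::summarise(correlation = mean(.data$correlation), .groups = "drop")
    # balanced mixture has the largest correlation; 1:0 equals a pure odorant
    expect_true(all(diff(ratio$correlation) < 0))
    cnt <- res$by_count |>
      dplyr::group_by(.data$n_components) |>
      dplyr::summarise(correlation = mean(.data$correlation), .groups = "drop")
    one_comp <- cnt$correlation[cnt$n_components == 1]
    expect_equal(ratio$correlation[ratio$fraction == 1], one_comp,
                 tolerance = 1e-10)
    expect_gt(cnt$correlation[cnt$n_components == 2], one_comp)
  }
})
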