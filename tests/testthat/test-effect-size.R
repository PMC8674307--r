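test_that("hedges_g reproduces the hand-worked example", {
  expect_equal(hedges_g(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(hedges_g(c(1, 2, 3), c(2, 3, 4), correct_bias = TRUE), -0.8)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
})

test_that("hedges_g agrees with the pooled t-statistic identity", {
  set.seed(42)
  for (rep in 1:5) {
    a <- rnorm(17, 0.3, 1.1)
    b <- rnorm(23, 0.0, 0.9)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    oracle <- unname(tt$statistic) * sqrt(1 / 17 + 1 / 23)
    expect_equal(hedges_g(a, b), oracle, tolerance = 1e-12)
  }
})

test_that("hedges_g is affine invariant and bias correction shrinks it", {
  set.seed(7)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  g <- hedges_g(a, b)
  expect_equal(hedges_g(3.2 * a - 1, 3.2 * b - 1), g, tolerance = 1e-12)
  expect_lt(abs(hedges_g(a, b, correct_bias = TRUE)), abs(g))
})

test_that("hedges_g rejects degenerate groups", {
  expect_error(hedges_g(c(1), c(2, 3)), ">= 2")
  expect_error(hedges_g(c(2, 2, 2), c(2, 2)), "Pooled standard deviation")
})

test_that("percent change follows the signed |original| convention", {
  expect_equal(percent_change(0.5, 0.5), 0)
  expect_equal(round_half_away(percent_change(0.1761, 0.3069), 1), -42.6)
  expect_equal(round_half_away(percent_change(0.2773, 0.2634), 1), 5.3)
  # negative original: base is |g_original|
  expect_equal(percent_change(-0.2, -0.4), 50)
  expect_error(percent_change(0.3, 0), "undefined")
})

test_that("round_half_away breaks ties away from zero", {
  expect_equal(round_half_away(c(0.25, -0.25, 2.45, -42.65), 1),
               c(0.3, -0.3, 2.5, -42.7))
  expect_equal(round_half_away(1.5, 0), 2)
})

test_that("feature_effect recovers a known group shift on one site", {
  cfg <- sim_config(sites = "A", n_per_site = 2000, patient_frac = 0.5,
                    n_features = 4, n_signal = 1, effect_size = 0.5,
                    site_shift = 0, tau = 0,
                    beta_age_mean = 0, beta_age_sd = 0,
                    beta_sex_mean = 0, beta_sex_sd = 0,
                    age_mean = 30, female_frac = 0.5, seed = 123)
  sim <- simulate_features(cfg)
  rep <- feature_effect(list(original = sim$features), sim$phenotypes,
                        features = sim$truth$signal_features)
  expect_lt(abs(rep$g - 0.5), 0.1)
  expect_equal(rep$percent_change, 0)
})

test_that("swd on a one-site cohort leaves every g identical", {
  cfg <- sim_config(sites = "A", n_per_site = 80, patient_frac = 0.5,
                    n_features = 6, n_signal = 2, site_shift = 0.3, tau = 0,
                    age_mean = 30, female_frac = 0.5, seed = 5)
  sim <- simulate_features(cfg)
  swd <- harmonize_swd(sim$features, sim$phenotypes)
  rep <- feature_effect(list(original = sim$features, swd = swd),
                        sim$phenotypes)
  wide <- tidyr::pivot_wider(rep[, c("feature", "method", "g")],
                             names_from = "method", values_from = "g")
  expect_equal(wide$swd, wide$original, tolerance = 1e-12)
})

test_that("report shape is features x methods with original at zero change", {
  ph <- toy_phenotypes(20, sites = rep(c("A", "B"), 10),
                       diagnosis = rep(c("control", "patient"), 10),
                       age = seq(20, 39), sex = rep(c(0L, 1L, 1L, 0L), 5))
  tbl <- random_features(ph, n_features = 5, seed = 3)
  tables <- list(original = tbl,
                 swd = harmonize_swd(tbl, ph),
                 glm = harmonize_glm(tbl, ph))
  rep <- feature_effect(tables, ph, features = c("f1", "f4"))
  expect_equal(nrow(rep), 2 * 3)
  expect_equal(rep$n_control, rep(10L, 6))
  expect_true(all(rep$percent_change[rep$method == "original"] == 0))
  expect_error(feature_effect(tables, ph, features = "nope"),
               "Unknown feature")
})
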