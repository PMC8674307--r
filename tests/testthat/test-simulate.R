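test_that("a fixed seed reproduces the cohort bit for bit", {
  cfg <- sim_config(seed = 77)
  a <- simulate_features(cfg)
  b <- simulate_features(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$gamma, b$truth$gamma)
  c <- simulate_features(sim_config(seed = 78))
  expect_false(identical(a$features, c$features))
})

test_that("the degenerate noiseless limit returns the baseline everywhere", {
  cfg <- sim_config(sites = c("A", "B"), n_per_site = c(4, 4),
                    patient_frac = c(0.5, 0.5), n_features = 6,
                    alpha_mean = 0.25, alpha_sd = 0.1,
                    beta_age_mean = 0, beta_age_sd = 0,
                    beta_sex_mean = 0, beta_sex_sd = 0,
                    n_signal = 0, effect_size = 0,
                    site_shift = c(0, 0), tau = 0, noise_sd = 0,
                    age_mean = c(30, 40), female_frac = c(0.5, 0.5), seed = 2)
  sim <- simulate_features(cfg)
  vals <- fc_values(sim$features)
  for (j in seq_len(nrow(vals))) {
    expect_equal(unname(vals[j, ]), sim$truth$alpha, tolerance = 1e-15)
  }
})

test_that("per-site feature means recover the generating site effects", {
  cfg <- sim_config(sites = c("A", "B", "C"), n_per_site = rep(200, 3),
                    patient_frac = rep(0.5, 3), n_features = 100,
                    beta_age_mean = 0, beta_age_sd = 0,
                    beta_sex_mean = 0, beta_sex_sd = 0,
                    n_signal = 0, effect_size = 0,
                    site_shift = c(-0.1, 0, 0.1), tau = 0.05,
                    age_mean = 35, female_frac = 0.5, seed = 31)
  sim <- simulate_features(cfg)
  vals <- fc_values(sim$features)
  se <- cfg$noise_sd / sqrt(200)
  within <- 0
  for (i in 1:3) {
    est <- colMeans(vals[sim$phenotypes$site == levels(sim$phenotypes$site)[i], ]) -
      sim$truth$alpha
    within <- within + sum(abs(est - sim$truth$gamma[i, ]) <= 3 * se)
  }
  expect_gt(within / (3 * 100), 0.98) # ~99.7% expected under normality
})

test_that("truth reconstructs the noiseless expectation of every cell", {
  cfg <- sim_config(sites = c("A", "B"), n_per_site = c(10, 10),
                    patient_frac = c(0.3, 0.7), n_features = 12,
                    site_shift = c(0.1, -0.1), tau = 0.02, seed = 6,
                    age_mean = c(30, 40), female_frac = c(0.4, 0.6))
  sim <- simulate_features(cfg)
  tr <- sim$truth
  ph <- sim$phenotypes
  idx <- as.integer(ph$site)
  expected <- outer(rep(1, nrow(ph)), tr$alpha) +
    outer(ph$age, tr$beta_age) + outer(ph$sex, tr$beta_sex) +
    outer(as.numeric(ph$diagnosis == "patient"), tr$d) +
    tr$gamma[idx, ]
  resid <- fc_values(sim$features) - expected
  # residuals are pure site-scaled noise: zero-mean, sd delta * noise_sd
  expect_lt(abs(mean(resid)), 4 * cfg$noise_sd / sqrt(length(resid)))
  expect_equal(sd(resid), cfg$noise_sd, tolerance = 0.1)
})

test_that("simulated time series converge to their target correlation", {
  ts <- simulate_timeseries(diag(10), 5000, seed = 8)[[1]]
  fc <- compute_fc(ts)
  expect_lt(max(abs(fc[upper.tri(fc)])), 0.05)

  target <- diag(4)
  target[1, 2] <- target[2, 1] <- 0.6
  fc2 <- compute_fc(simulate_timeseries(target, 5000, seed = 9)[[1]])
  expect_lt(abs(fc2[1, 2] - 0.6), 0.05)

  bad <- matrix(1, 3, 3) # rank 1, not positive definite
  expect_error(simulate_timeseries(bad, 100), "positive definite")

  # T = 2 generation is permitted; FC computation on it is not
  short <- simulate_timeseries(diag(3), 2, seed = 1)[[1]]
  expect_equal(nrow(short$values), 2)
  expect_error(compute_fc(short), "3 timepoints")
})

test_that("config validation rejects impossible cohorts", {
  expect_error(sim_config(n_per_site = c(0, 10, 10, 10)), "positive")
  expect_error(sim_config(patient_frac = c(0.5, 0.5, 0.5, 1.2)), "0, 1")
  expect_error(sim_config(n_features = 5, n_signal = 10, n_regions = NULL),
               "n_signal")
  expect_error(sim_config(site_shift = c(1, 2)), "one value per site")
})
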