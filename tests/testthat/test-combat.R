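small_combat_cohort <- function(seed = 11) {
  cfg <- sim_config(
    sites = c("S1", "S2", "S3"), n_per_site = c(10, 10, 10),
    patient_frac = c(0.5, 0.5, 0.5), n_features = 20, n_signal = 2,
    site_shift = c(0.1, -0.05, 0.05), tau = 0.03,
    site_scale = c(1, 1.2, 0.9), site_scale_spread = 0.2,
    age_mean = c(30, 35, 40), female_frac = 0.5, seed = seed
  )
  simulate_features(cfg)
}

test_that("combat matches the independent sva reference per entry", {
  sim <- small_combat_cohort()
  h <- harmonize_combat(sim$features, sim$phenotypes)
  Y <- fc_values(sim$features)
  mod <- stats::model.matrix(~ age + sex + I(diagnosis == "patient"),
                             data = sim$phenotypes)
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(Y), batch = sim$phenotypes$site, mod = mod)
  ))
  expect_lt(max(abs(fc_values(h$table) - ref)), 1e-6)
})

test_that("the EB fixed point satisfies both update equations", {
  sim <- small_combat_cohort(seed = 3)
  h <- harmonize_combat(sim$features, sim$phenotypes)
  p <- h$parameters
  site <- sim$phenotypes$site
  Y <- fc_values(sim$features)
  M <- cbind(sim$phenotypes$age, sim$phenotypes$sex,
             as.numeric(sim$phenotypes$diagnosis == "patient"))
  Z <- (Y - outer(rep(1, nrow(Y)), p$alpha) -
          M %*% t(as.matrix(p$beta[, -1]))) /
    outer(rep(1, nrow(Y)), sqrt(p$sigma2))
  for (i in seq_len(nrow(p$gamma_star))) {
    lev <- p$hyper$site[i]
    Zi <- Z[site == lev, , drop = FALSE]
    ni <- nrow(Zi)
    g <- p$gamma_star[i, ]; d2 <- p$delta2_star[i, ]
    g_next <- (p$hyper$tau2[i] * ni * p$gamma_hat[i, ] +
                 d2 * p$hyper$gamma_bar[i]) / (p$hyper$tau2[i] * ni + d2)
    d2_next <- (p$hyper$theta[i] +
                  0.5 * colSums(sweep(Zi, 2, g_next)^2)) /
      (ni / 2 + p$hyper$lambda[i] - 1)
    expect_lt(max(abs(g_next - g)), 1e-3)
    expect_lt(max(abs(d2_next - d2) / d2), 1e-3)
    expect_gt(p$hyper$iterations[i], 0)
  }
})

test_that("combat preserves shape, order, and finiteness of parameters", {
  sim <- small_combat_cohort(seed = 4)
  h <- harmonize_combat(sim$features, sim$phenotypes)
  expect_equal(dim(h$table), dim(sim$features))
  expect_identical(h$table$subject_id, sim$features$subject_id)
  expect_true(all(is.finite(fc_values(h$table))))
  expect_true(all(vapply(
    h$parameters[c("alpha", "sigma2", "gamma_star", "delta2_star")],
    function(x) all(is.finite(as.matrix(x))), logical(1)
  )))
  expect_equal(fc_provenance(h$table),
               c("simulated", "fisher_z", "combat"))
})

test_that("without site effects combat leaves the data nearly unchanged", {
  cfg <- sim_config(sites = paste0("S", 1:4), n_per_site = rep(50, 4),
                    patient_frac = 0.5, n_features = 500, n_signal = 5,
                    effect_size = 0.8, site_shift = rep(0, 4), tau = 0,
                    age_mean = 35, female_frac = 0.5, seed = 9)
  sim <- simulate_features(cfg)
  h <- harmonize_combat(sim$features, sim$phenotypes)
  d <- fc_values(h$table) - fc_values(sim$features)
  expect_lt(sqrt(mean(d^2)), 0.05)
  expect_gt(cor(as.vector(fc_values(h$table)),
                as.vector(fc_values(sim$features))), 0.99)
})

test_that("combat equalizes per-feature site means on location-shift data", {
  cfg <- sim_config(sites = paste0("S", 1:3), n_per_site = rep(60, 3),
                    patient_frac = 0.5, n_features = 100, n_signal = 2,
                    site_shift = c(-0.2, 0, 0.2), tau = 0.05,
                    age_mean = 35, female_frac = 0.5, seed = 14)
  sim <- simulate_features(cfg)
  h <- harmonize_combat(sim$features, sim$phenotypes)
  gap <- function(M) {
    sm <- sapply(levels(sim$phenotypes$site),
                 function(l) colMeans(M[sim$phenotypes$site == l, , drop = FALSE]))
    mean(apply(sm, 1, function(x) max(x) - min(x)))
  }
  expect_lt(gap(fc_values(h$table)), gap(fc_values(sim$features)) / 5)
})

test_that("single-subject sites are rejected", {
  ph <- toy_phenotypes(5, sites = c("A", "A", "A", "A", "B"),
                       diagnosis = c("control", "patient", "control",
                                     "patient", "control"),
                       age = c(20, 30, 40, 50, 60), sex = c(0L, 1L, 0L, 1L, 0L))
  tbl <- random_features(ph, n_features = 3, seed = 2)
  expect_error(harmonize_combat(tbl, ph), ">= 2 subjects per site.*B")
})
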