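balanced_cohort <- function(n_per_cell = 5) {
  # two sites x two diagnosis groups, fully balanced
  grid <- expand.grid(site = c("A", "B"),
                      diagnosis = c("control", "patient"),
                      k = seq_len(n_per_cell))
  toy_phenotypes(nrow(grid), sites = as.character(grid$site),
                 diagnosis = as.character(grid$diagnosis),
                 age = seq(20, 19 + nrow(grid)),
                 sex = rep(c(0L, 1L, 1L, 0L), length.out = nrow(grid)))
}

test_that("site-only mode exactly removes constructed pure site offsets", {
  ph <- balanced_cohort(5)
  offsets <- c(A = 0.5, B = -0.3)
  d <- 0.4 # noise-free group signal, identical at both sites
  y1 <- offsets[as.character(ph$site)] + d * (ph$diagnosis == "patient")
  y2 <- offsets[as.character(ph$site)] - 0.1 * (ph$diagnosis == "patient")
  tbl <- toy_features(cbind(f1 = unname(y1), f2 = unname(y2)), ph,
                      provenance = "fisher_z")
  h <- harmonize_glm(tbl, ph, mode = "site-only", covariates = character(0))
  # after removal every subject sits at the reference-site level + group signal
  expect_equal(h$table$f1,
               unname(offsets["A"] + d * (ph$diagnosis == "patient")),
               tolerance = 1e-12)
  expect_equal(h$table$f2,
               unname(offsets["A"] - 0.1 * (ph$diagnosis == "patient")),
               tolerance = 1e-12)
  # estimated site coefficient recovers the constructed offset difference
  coef_b <- h$parameters$coefficients$siteB
  expect_equal(coef_b, rep(offsets[["B"]] - offsets[["A"]], 2), tolerance = 1e-12)
})

test_that("with no site effect the full-mode output equals covariate residuals", {
  ph <- balanced_cohort(6)
  y <- 0.2 - 0.003 * ph$age + 0.04 * ph$sex # exactly linear, no site term
  tbl <- toy_features(cbind(f1 = y), ph, provenance = "fisher_z")
  h <- harmonize_glm(tbl, ph, mode = "full")
  pure <- residualize_covariates(tbl, ph, keep_level = FALSE)
  expect_equal(h$table$f1, pure$f1, tolerance = 1e-12)
  expect_equal(h$table$f1, rep(0, nrow(ph)), tolerance = 1e-12)
})

test_that("full-mode residuals are orthogonal to every design column", {
  ph <- toy_phenotypes(60, sites = rep(c("A", "B", "C"), 20),
                       diagnosis = rep(c("control", "patient"), 30),
                       age = seq(18, 77), sex = rep(c(0L, 1L, 1L, 0L), 15))
  tbl <- random_features(ph, n_features = 9, seed = 23,
                         provenance = "fisher_z")
  h <- harmonize_glm(tbl, ph, mode = "full")
  vals <- fc_values(h$table)
  design <- cbind(age = ph$age, sex = ph$sex,
                  siteB = as.numeric(ph$site == "B"),
                  siteC = as.numeric(ph$site == "C"))
  for (v in seq_len(ncol(vals))) {
    for (cc in seq_len(ncol(design))) {
      expect_lt(abs(cor(vals[, v], design[, cc])), 1e-10)
    }
  }
})

test_that("glm requires multiple sites and a full-rank design", {
  ph <- toy_phenotypes(10, sites = rep("A", 10),
                       diagnosis = rep(c("control", "patient"), 5),
                       age = seq(20, 29), sex = rep(c(0L, 1L), 5))
  tbl <- random_features(ph, n_features = 2, seed = 5)
  expect_error(harmonize_glm(tbl, ph), "two sites")

  ph2 <- toy_phenotypes(10, sites = rep(c("A", "B"), each = 5),
                        diagnosis = rep("control", 10),
                        age = seq(30, 39), sex = rep(c(0L, 1L), 5))
  ph2$age <- ifelse(ph2$site == "A", 20, 40) # site determines age exactly
  tbl2 <- random_features(ph2, n_features = 2, seed = 6)
  expect_error(harmonize_glm(tbl2, ph2), "rank deficient")
})
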