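#' Parametric empirical-Bayes ComBat harmonization
#'
#' Location/scale batch-effect harmonization for FC feature tables. The model
#' for feature `v` of subject `j` at site `i` is
#' `y_ijv = alpha_v + X_ij' beta_v + gamma_iv + delta_iv * eps_ijv`,
#' with `gamma` the additive (location) and `delta` the multiplicative
#' (scale) site effect. Estimation follows the standard parametric
#' empirical-Bayes scheme:
#'
#' 1. per feature, OLS with site indicators under the constraint
#'    `sum_i n_i gamma_i = 0`, and a pooled residual variance
#'    `sigma_v^2` with a `1/n` denominator;
#' 2. standardize `z = (y - alpha - X beta) / sigma_v`;
#' 3. per site, method-of-moments hyperparameters across features -- normal
#'    prior for the per-feature site means, inverse-gamma for the per-feature
#'    site variances -- and iterated conditional posterior updates of
#'    `gamma*` and `delta*^2` until the largest relative change falls below
#'    `conv`;
#' 4. adjust `y* = sigma_v * (z - gamma*) / delta* + alpha_v + X_ij' beta_v`.
#'
#' The covariate design protects age, sex and diagnosis (the covariates of
#' interest), so their effects are reinserted in step 4. Optionally the
#' harmonized table then has age and sex regressed out again via
#' [residualize_covariates()], the order used when feeding effect-size
#' comparisons.
#'
#' @param features Feature table (Fisher-z scale).
#' @param phenotypes Aligned phenotype table (site, age, sex, diagnosis).
#' @param covariates Covariates of interest kept in the model (default age,
#'   sex, diagnosis).
#' @param adjust_covariates Regress age and sex out of the harmonized table
#'   afterwards (default `FALSE`).
#' @param conv Convergence threshold for the largest relative change in the
#'   EB updates (default `1e-4`, the convention of reference parametric
#'   ComBat implementations).
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   worst remaining change.
#' @return An `fc_harmony` object. `$parameters` holds `alpha`, the
#'   per-feature covariate coefficients, `sigma2`, the raw (`gamma_hat`,
#'   `delta2_hat`) and EB-shrunk (`gamma_star`, `delta2_star`) site effects
#'   (sites x features, standardized scale), `gamma_star_data` on the data
#'   scale, and the per-site hyperparameters with iteration counts.
#' @export
harmonize_combat <- function(features, phenotypes,
                             covariates = c("age", "sex", "diagnosis"),
                             adjust_covariates = FALSE,
                             conv = 1e-4, max_iter = 500) {
  site <- site_grouping(features, phenotypes)
  n_i <- table(site)
  if (any(n_i < 2)) {
    abort(paste0("ComBat needs >= 2 subjects per site; offending site(s): ",
                 toString(names(n_i)[n_i < 2]), "."))
  }
  Y <- fc_values(features)
  n <- nrow(Y); V <- ncol(Y)
  lev <- levels(site)
  I <- length(lev)

  # step 1: joint OLS with one indicator per site (no intercept) + covariates
  B <- vapply(lev, function(s) as.numeric(site == s), numeric(n))
  M <- build_design(phenotypes, terms = covariates, intercept = FALSE)
  X <- cbind(B, M)
  colnames(X) <- c(lev, colnames(M))
  if (qr(X)$rank < ncol(X)) {
    abort("ComBat design (site indicators + covariates) is rank deficient.")
  }
  fit <- ols_fit(X, Y)
  Bhat <- fit$coefficients
  w <- as.numeric(n_i) / n
  alpha <- drop(w %*% Bhat[seq_len(I), , drop = FALSE])   # sum_i n_i gamma_i = 0
  sigma2 <- colSums((Y - X %*% Bhat)^2) / n
  if (any(sigma2 <= 0)) {
    abort("Zero pooled residual variance for some feature; cannot standardize.")
  }

  # step 2: standardize, keeping covariate effects in the reference mean
  stand_mean <- outer(rep(1, n), alpha) +
    M %*% Bhat[-seq_len(I), , drop = FALSE]
  Z <- (Y - stand_mean) / outer(rep(1, n), sqrt(sigma2))

  # step 3: per-site moments and EB shrinkage
  gamma_hat <- matrix(NA_real_, I, V, dimnames = list(lev, colnames(Y)))
  delta2_hat <- gamma_hat
  for (i in seq_len(I)) {
    Zi <- Z[site == lev[i], , drop = FALSE]
    gamma_hat[i, ] <- colMeans(Zi)
    delta2_hat[i, ] <- colSums(sweep(Zi, 2, gamma_hat[i, ])^2) / (nrow(Zi) - 1)
  }
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, var)
  m_d <- rowMeans(delta2_hat)
  s2_d <- apply(delta2_hat, 1, var)
  lambda <- (m_d^2 + 2 * s2_d) / s2_d          # inverse-gamma shape
  theta <- (m_d * s2_d + m_d^3) / s2_d         # inverse-gamma rate

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  iterations <- integer(I)
  for (i in seq_len(I)) {
    Zi <- Z[site == lev[i], , drop = FALSE]
    ni <- nrow(Zi)
    g_hat <- gamma_hat[i, ]; d_hat <- delta2_hat[i, ]
    g_old <- g_hat; d_old <- d_hat
    change <- Inf; count <- 0L
    while (change > conv) {
      if (count >= max_iter) {
        abort(sprintf(
          "ComBat EB updates for site '%s' did not converge in %d iterations (worst relative change %.3g).",
          lev[i], max_iter, change
        ))
      }
      g_new <- (tau2[i] * ni * g_hat + d_old * gamma_bar[i]) /
        (tau2[i] * ni + d_old)
      sum2 <- colSums(sweep(Zi, 2, g_new)^2)
      d_new <- (theta[i] + 0.5 * sum2) / (ni / 2 + lambda[i] - 1)
      change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      count <- count + 1L
    }
    gamma_star[i, ] <- g_old
    delta2_star[i, ] <- d_old
    iterations[i] <- count
  }

  # step 4: adjust
  idx <- as.integer(site)
  Ystar <- (Z - gamma_star[idx, , drop = FALSE]) /
    sqrt(delta2_star)[idx, , drop = FALSE]
  Ystar <- Ystar * outer(rep(1, n), sqrt(sigma2)) + stand_mean
  dimnames(Ystar) <- dimnames(Y)

  tbl <- fc_rebuild(features, Ystar, add_step = "combat")
  params <- list(
    alpha = alpha,
    beta = tibble::as_tibble(t(Bhat[-seq_len(I), , drop = FALSE]),
                             rownames = "feature"),
    sigma2 = sigma2,
    gamma_hat = gamma_hat,
    delta2_hat = delta2_hat,
    gamma_star = gamma_star,
    delta2_star = delta2_star,
    gamma_star_data = gamma_star * outer(rep(1, I), sqrt(sigma2)),
    hyper = tibble::tibble(
      site = lev, n = as.integer(n_i), gamma_bar = gamma_bar,
      tau2 = tau2, lambda = lambda, theta = theta, iterations = iterations
    )
  )
  res <- new_fc_harmony(tbl, "combat", parameters = params,
                        details = list(conv = conv, covariates = covariates))
  if (adjust_covariates) {
    res$table <- residualize_covariates(res$table, phenotypes,
                                        covariates = c("age", "sex"))
  }
  res
}
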