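#' Configuration for the multi-site FC cohort simulator
#'
#' Defines the generative model
#' `y_ijv = alpha_v + age_j * beta_age_v + sex_j * beta_sex_v
#'  + diag_j * d_v + gamma_iv + delta_iv * eps_ijv`
#' on the Fisher-z scale, with `eps ~ N(0, noise_sd)`. Defaults describe a
#' small four-site case-control cohort whose diagnosis imbalance, age
#' structure and sex mix follow the published demographics of a four-site
#' schizophrenia consortium, at a size convenient for testing.
#'
#' @param sites Site labels.
#' @param n_per_site Subjects per site.
#' @param patient_frac Per-site probability of a patient diagnosis.
#' @param n_features Number of FC features `V`; alternatively give
#'   `n_regions` and `V = R(R-1)/2` is used.
#' @param n_regions Optional region count implying `n_features`.
#' @param alpha_mean,alpha_sd Normal distribution of per-feature baselines
#'   `alpha_v` (Fisher-z units).
#' @param beta_age_mean,beta_age_sd Per-feature age slopes (z units / year).
#' @param beta_sex_mean,beta_sex_sd Per-feature sex effects (z units,
#'   female - male).
#' @param n_signal Number of "signal" features carrying the diagnosis
#'   effect (the first `n_signal` features).
#' @param effect_size Diagnosis effect on signal features, in within-group
#'   SD units; positive means controls exceed patients (hypoconnectivity in
#'   patients).
#' @param site_shift Per-site mean additive effects `Gamma_i` (z units), or
#'   `NULL` to draw them as `N(0, site_shift_sd)`.
#' @param site_shift_sd SD used when drawing `Gamma_i` (default 0.1).
#' @param tau SD of per-feature location effects around the site mean:
#'   `gamma_iv ~ N(Gamma_i, tau^2)`. `tau = 0` gives pure per-site offsets.
#' @param site_scale Per-site mean multiplicative effects `delta_i`
#'   (default all 1 = no scale effect).
#' @param site_scale_spread If positive, per-feature `delta_iv^2` are drawn
#'   from an inverse-gamma with mean `site_scale_i^2` and this coefficient
#'   of variation; 0 keeps them fixed at `site_scale_i`.
#' @param noise_sd Within-group residual SD on the z scale.
#' @param age_mean Per-site mean ages; `age ~ N(age_mean_i, age_sd)`.
#' @param age_sd Within-site age SD.
#' @param female_frac Per-site probability of female sex.
#' @param seed Integer seed; the seed fully determines the cohort. Separate
#'   streams are derived for phenotypes, parameters, and noise so changing
#'   one block does not perturb the others.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(sites = c("A", "B", "C", "D"),
                       n_per_site = c(40, 60, 40, 60),
                       patient_frac = c(0.71, 0.65, 0.59, 0.71),
                       n_features = NULL,
                       n_regions = if (is.null(n_features)) 20 else NULL,
                       alpha_mean = 0.25, alpha_sd = 0.1,
                       beta_age_mean = -0.002, beta_age_sd = 0.001,
                       beta_sex_mean = 0.02, beta_sex_sd = 0.01,
                       n_signal = 5, effect_size = 0.8,
                       site_shift = NULL, site_shift_sd = 0.1,
                       tau = 0.05,
                       site_scale = rep(1, length(sites)),
                       site_scale_spread = 0,
                       noise_sd = 0.2,
                       age_mean = c(38.7, 34.7, 39.6, 33.9),
                       age_sd = 12,
                       female_frac = c(0.47, 0.5, 0.56, 0.48),
                       seed = 1L) {
  if (is.null(n_features)) n_features <- n_regions * (n_regions - 1) / 2
  I <- length(sites)
  rec <- function(x) if (length(x) == 1) rep(x, I) else x
  cfg <- list(
    sites = as.character(sites),
    n_per_site = rec(n_per_site), patient_frac = rec(patient_frac),
    n_features = as.integer(n_features),
    alpha_mean = alpha_mean, alpha_sd = alpha_sd,
    beta_age_mean = beta_age_mean, beta_age_sd = beta_age_sd,
    beta_sex_mean = beta_sex_mean, beta_sex_sd = beta_sex_sd,
    n_signal = as.integer(n_signal), effect_size = effect_size,
    site_shift = site_shift, site_shift_sd = site_shift_sd, tau = tau,
    site_scale = rec(site_scale), site_scale_spread = site_scale_spread,
    noise_sd = noise_sd,
    age_mean = rec(age_mean), age_sd = age_sd,
    female_frac = rec(female_frac),
    seed = as.integer(seed)
  )
  lens <- lengths(cfg[c("n_per_site", "patient_frac", "site_scale",
                        "age_mean", "female_frac")])
  if (any(lens != I)) abort("Per-site fields must have one value per site.")
  if (any(cfg$n_per_site < 1)) abort("Subject counts must be positive.")
  if (any(cfg$patient_frac < 0 | cfg$patient_frac > 1)) {
    abort("`patient_frac` must lie in [0, 1].")
  }
  if (cfg$n_signal > cfg$n_features) {
    abort("`n_signal` cannot exceed `n_features`.")
  }
  if (!is.null(cfg$site_shift) && length(cfg$site_shift) != I) {
    abort("`site_shift` must have one value per site.")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` cannot be negative.")
  structure(cfg, class = "sim_config")
}

#' Headline four-site cohort configuration
#'
#' The study conditions for the comparative SWD / GLM / ComBat evaluation:
#' four sites with the diagnosis imbalance of the published four-site
#' schizophrenia cohort (patient fractions 0.59-0.71) and its relative site
#' sizes scaled up (n = 5,072 per replicate), fixed additive site offsets
#' whose weighted spread is comparable to the GLM imbalance-absorption
#' fraction and which are uncorrelated with the diagnosis-imbalance
#' contrast, no scale effects, and one signal feature carrying a large
#' (1 SD) diagnosis effect among 50 features. The size is chosen so the
#' method comparison reflects the harmonizers rather than sampling noise.
#'
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
sim_config_headline <- function(seed = 1L) {
  sim_config(
    sites = c("Baltimore", "Boston", "Dallas", "Hartford"),
    n_per_site = 16L * c(188L, 52L, 143L, 129L),
    patient_frac = c(0.713, 0.654, 0.594, 0.705),
    n_features = 50,
    n_signal = 1, effect_size = 1,
    site_shift = c(0.0218, -0.0313, 0.0073, -0.0273),
    tau = 0,
    noise_sd = 0.2,
    age_mean = c(38.7, 34.7, 39.6, 33.9),
    female_frac = c(0.472, 0.5, 0.559, 0.481),
    seed = seed
  )
}

with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed + offset * 1000003L) %% .Machine$integer.max)
  expr
}

#' Simulate a multi-site FC feature cohort with known ground truth
#'
#' Draws phenotypes, model parameters and noise from the generative model of
#' [sim_config()] and returns the Fisher-z feature table, the phenotype
#' table, and a `truth` list with every drawn parameter -- enough to
#' reconstruct the noiseless expectation of every cell and to run parameter-
#' recovery checks against the harmonizers.
#'
#' @param config A [sim_config()].
#' @return A list with elements `features` (tibble, provenance
#'   `c("simulated", "fisher_z")`), `phenotypes` (tibble), and `truth`
#'   (list: `alpha`, `beta_age`, `beta_sex`, `gamma` (sites x features),
#'   `delta` (sites x features), `d` (per-feature diagnosis shift on the
#'   data scale), `signal_features`, `site_shift`, `config`).
#' @export
simulate_features <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  I <- length(config$sites)
  V <- config$n_features
  n <- sum(config$n_per_site)
  seed <- config$seed

  phenotypes <- with_stream(seed, 1L, {
    site <- rep(config$sites, config$n_per_site)
    age <- unlist(lapply(seq_len(I), function(i) {
      rnorm(config$n_per_site[i], config$age_mean[i], config$age_sd)
    }))
    sex <- unlist(lapply(seq_len(I), function(i) {
      rbinom(config$n_per_site[i], 1, config$female_frac[i])
    }))
    diagnosis <- unlist(lapply(seq_len(I), function(i) {
      rbinom(config$n_per_site[i], 1, config$patient_frac[i])
    }))
    tibble::tibble(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      site = factor(site, levels = config$sites),
      diagnosis = factor(ifelse(diagnosis == 1, "patient", "control"),
                         levels = c("control", "patient")),
      age = round(age, 1), sex = as.integer(sex)
    )
  })

  truth <- with_stream(seed, 2L, {
    alpha <- rnorm(V, config$alpha_mean, config$alpha_sd)
    beta_age <- rnorm(V, config$beta_age_mean, config$beta_age_sd)
    beta_sex <- rnorm(V, config$beta_sex_mean, config$beta_sex_sd)
    Gamma <- config$site_shift %||% rnorm(I, 0, config$site_shift_sd)
    gamma <- Gamma + if (config$tau > 0) {
      matrix(rnorm(I * V, 0, config$tau), I, V)
    } else {
      matrix(0, I, V)
    }
    delta <- matrix(rep(config$site_scale, V), I, V)
    if (config$site_scale_spread > 0) {
      cv <- config$site_scale_spread
      shape <- 1 / cv^2 + 2
      for (i in seq_len(I)) {
        rate <- config$site_scale[i]^2 * (shape - 1)
        delta[i, ] <- sqrt(rate / rgamma(V, shape = shape))
      }
    }
    d <- numeric(V)
    sig <- seq_len(config$n_signal)
    d[sig] <- -config$effect_size * config$noise_sd  # patients lower
    dimnames(gamma) <- dimnames(delta) <-
      list(config$sites, feature_names_for(V))
    list(alpha = alpha, beta_age = beta_age, beta_sex = beta_sex,
         site_shift = Gamma, gamma = gamma, delta = delta, d = d,
         signal_features = feature_names_for(V)[sig], config = config)
  })

  values <- with_stream(seed, 3L, {
    eps <- matrix(rnorm(n * V, 0, config$noise_sd), n, V)
    idx <- as.integer(phenotypes$site)
    dx <- as.numeric(phenotypes$diagnosis == "patient")
    outer(rep(1, n), truth$alpha) +
      outer(phenotypes$age, truth$beta_age) +
      outer(phenotypes$sex, truth$beta_sex) +
      outer(dx, truth$d) +
      truth$gamma[idx, , drop = FALSE] +
      truth$delta[idx, , drop = FALSE] * eps
  })
  colnames(values) <- feature_names_for(V)

  features <- dplyr::bind_cols(
    tibble::tibble(subject_id = phenotypes$subject_id),
    tibble::as_tibble(values)
  )
  fc_provenance(features) <- c("simulated", "fisher_z")
  list(features = features, phenotypes = phenotypes, truth = truth)
}

# "a_b" names when V is a full upper triangle, else "f1".."fV"
feature_names_for <- function(V) {
  r <- (1 + sqrt(1 + 8 * V)) / 2
  if (abs(r - round(r)) < 1e-8) feature_pairs(round(r))$feature
  else paste0("f", seq_len(V))
}

#' Simulate regional time series with a target correlation structure
#'
#' Draws `n_timepoints` observations from a zero-mean multivariate normal
#' whose correlation matrix is `target`; the empirical FC converges to the
#' target as the series lengthens.
#'
#' @param target Positive-definite R x R correlation matrix.
#' @param n_timepoints Number of timepoints T.
#' @param subject_ids Character vector; one `roi_ts` is generated per ID.
#' @param seed Integer seed.
#' @return A named list of [roi_timeseries()] objects.
#' @export
simulate_timeseries <- function(target, n_timepoints, subject_ids = "sim-01",
                                seed = 1L) {
  target <- as.matrix(target)
  if (nrow(target) != ncol(target) || any(abs(target - t(target)) > 1e-10)) {
    abort("`target` must be a symmetric square matrix.")
  }
  L <- tryCatch(chol(target), error = function(e) {
    abort("`target` correlation matrix is not positive definite.")
  })
  R <- nrow(target)
  out <- with_stream(seed, 4L, {
    lapply(seq_along(subject_ids), function(k) {
      Z <- matrix(rnorm(n_timepoints * R), n_timepoints, R)
      roi_timeseries(Z %*% L, subject_id = subject_ids[k])
    })
  })
  names(out) <- subject_ids
  out
}
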