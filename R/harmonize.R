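new_fc_harmony <- function(table, method, parameters, details = list()) {
  structure(
    list(table = table, method = method, parameters = parameters,
         details = details),
    class = "fc_harmony"
  )
}

#' @export
print.fc_harmony <- function(x, ...) {
  cat(sprintf("<fc_harmony> method '%s': %d subjects x %d features\n",
              x$method, nrow(x$table), length(feature_cols(x$table))))
  cat("provenance:", paste(fc_provenance(x$table), collapse = " -> "), "\n")
  invisible(x)
}

site_grouping <- function(features, phenotypes) {
  check_feature_table(features)
  check_aligned(features, phenotypes)
  site <- as.factor(phenotypes$site) # keeps declared-but-unused levels
  counts <- table(site)
  if (any(counts == 0)) {
    abort(paste0("Empty site level(s): ",
                 toString(names(counts)[counts == 0]),
                 ". Drop unused site levels before harmonizing."))
  }
  site
}

#' Site-wise de-meaning (SWD) harmonization
#'
#' Computes one scalar per site -- the mean of all FC values over every
#' subject and every feature at that site -- and subtracts it from each of
#' that site's values. Because a single scalar is removed per site, within-
#' site group contrasts (and hence single-site effect sizes) are untouched,
#' while additive between-site offsets are removed. Intended for Fisher-z
#' tables with age and sex already regressed out (see
#' [residualize_covariates()]).
#'
#' @param features Feature table (subjects x features).
#' @param phenotypes Phenotype table aligned with `features` (site column).
#' @return An `fc_harmony` object; `$parameters$site_means` holds the per-site
#'   scalar means.
#' @export
harmonize_swd <- function(features, phenotypes) {
  site <- site_grouping(features, phenotypes)
  singles <- names(which(table(site) == 1))
  if (length(singles) > 0) {
    warn(paste0("Site(s) with a single subject (mean is degenerate): ",
                toString(singles), "."))
  }
  Y <- fc_values(features)
  means <- vapply(levels(site), function(s) mean(Y[site == s, , drop = FALSE]),
                  numeric(1))
  out <- Y - means[as.character(site)]
  tbl <- fc_rebuild(features, out, add_step = "swd")
  new_fc_harmony(
    tbl, "swd",
    parameters = list(site_means = tibble::tibble(
      site = levels(site), n = as.integer(table(site)),
      mean = unname(means)
    ))
  )
}

#' GLM site-effect removal
#'
#' Fits, per feature, `y ~ intercept + age + sex + site` by ordinary least
#' squares (site as reference-coded indicators, no diagnosis term). In the
#' default `"full"` mode the entire fitted value is subtracted, leaving the
#' OLS residuals; in `"site-only"` mode only the fitted site-indicator
#' component is subtracted, so age and sex components stay in the data.
#'
#' @param features Feature table (Fisher-z scale).
#' @param phenotypes Aligned phenotype table (site, age, sex).
#' @param mode `"full"` (subtract the whole fitted value) or `"site-only"`.
#' @param covariates Non-site covariates entering the design (default age,
#'   sex).
#' @return An `fc_harmony` object; `$parameters$coefficients` holds the
#'   per-feature estimates (intercept, covariates, site indicators).
#' @export
harmonize_glm <- function(features, phenotypes,
                          mode = c("full", "site-only"),
                          covariates = c("age", "sex")) {
  mode <- match.arg(mode)
  site <- site_grouping(features, phenotypes)
  if (nlevels(droplevels(site)) < 2) {
    abort("GLM site removal needs at least two sites.")
  }
  Y <- fc_values(features)
  X <- build_design(phenotypes, terms = c(covariates, "site"), intercept = TRUE)
  if (nrow(X) <= ncol(X)) {
    abort(sprintf("Need more subjects (%d) than design columns (%d).",
                  nrow(X), ncol(X)))
  }
  fit <- ols_fit(X, Y)
  B <- fit$coefficients
  if (mode == "full") {
    out <- fit$residuals
  } else {
    site_cols <- grep("^site", colnames(X))
    out <- Y - X[, site_cols, drop = FALSE] %*% B[site_cols, , drop = FALSE]
  }
  dimnames(out) <- dimnames(Y)
  coefs <- tibble::as_tibble(t(B), rownames = "feature")
  tbl <- fc_rebuild(features, out,
                    add_step = if (mode == "full") "glm_full" else "glm_site")
  new_fc_harmony(tbl, "glm",
                 parameters = list(coefficients = coefs),
                 details = list(mode = mode, design_columns = colnames(X)))
}
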