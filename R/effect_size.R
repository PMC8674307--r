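#' Hedges' g between two groups
#'
#' Standardized mean difference `(mean(control) - mean(patient)) / sd_pooled`
#' with the `(n-1)`-weighted pooled standard deviation
#' `sd_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' Positive values mean controls exceed patients. With
#' `correct_bias = TRUE` the small-sample correction
#' `J = 1 - 3 / (4 (n1 + n2 - 2) - 1)` is applied; the default leaves it off
#' (the correction is negligible at multi-site sample sizes and cancels from
#' percent-change comparisons).
#'
#' @param control_values,patient_values Numeric vectors (each length >= 2).
#' @param correct_bias Apply the small-sample bias correction.
#' @return A single numeric effect size.
#' @examples
#' hedges_g(c(1, 2, 3), c(2, 3, 4))                      # -1
#' hedges_g(c(1, 2, 3), c(2, 3, 4), correct_bias = TRUE) # -0.8
#' @export
hedges_g <- function(control_values, patient_values, correct_bias = FALSE) {
  n1 <- length(control_values); n2 <- length(patient_values)
  if (n1 < 2 || n2 < 2) {
    abort(sprintf("Both groups need >= 2 observations (got %d and %d).", n1, n2))
  }
  s1 <- var(control_values); s2 <- var(patient_values)
  sd_pooled <- sqrt(((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2))
  if (sd_pooled == 0) {
    abort("Pooled standard deviation is zero; effect size undefined.")
  }
  g <- (mean(control_values) - mean(patient_values)) / sd_pooled
  if (correct_bias) g <- g * (1 - 3 / (4 * (n1 + n2 - 2) - 1))
  g
}

#' Percent change of an effect size relative to the unharmonized data
#'
#' `100 * (g_method - g_original) / |g_original|`: the signed percent
#' increase (positive) or decrease (negative) in effect size a harmonization
#' method produces relative to the original data. Values are returned at full
#' precision; reporting layers round to one decimal with
#' [round_half_away()].
#'
#' @param g_method Effect size after harmonization.
#' @param g_original Effect size of the original data (non-zero).
#' @return Signed percent change (vectorized).
#' @export
percent_change <- function(g_method, g_original) {
  if (any(g_original == 0)) {
    abort("Percent change is undefined when the original effect size is 0.")
  }
  100 * (g_method - g_original) / abs(g_original)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so -42.65 -> -42.7),
#' the convention used for reported percent changes; base `round()` rounds
#' half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

as_feature_table <- function(x) {
  if (inherits(x, "fc_harmony")) x$table else x
}

#' Per-feature effect-size report across harmonization methods
#'
#' Computes Hedges' g of the control vs patient contrast for each requested
#' feature under each method's table, plus the percent change of each
#' method relative to `"original"` (which must be one of the supplied
#' tables). This mirrors the layout of published method-comparison tables:
#' one row per feature and method, with g, group sizes, and percent change.
#'
#' @param tables Named list of feature tables (or `fc_harmony` objects);
#'   must include an `"original"` element when percent changes are wanted.
#' @param phenotypes Phenotype table aligned with every element of `tables`.
#' @param features Character vector of feature names (e.g. `"0_2"`), or
#'   `NULL` for all features.
#' @param correct_bias Passed to [hedges_g()].
#' @return A tibble with columns `feature`, `method`, `n_control`,
#'   `n_patient`, `g`, `percent_change` (0 for `"original"`, `NA` when no
#'   original table was supplied).
#' @export
feature_effect <- function(tables, phenotypes, features = NULL,
                           correct_bias = FALSE) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("`tables` must be a named list, e.g. list(original = ..., swd = ...).")
  }
  tables <- lapply(tables, as_feature_table)
  for (nm in names(tables)) check_aligned(tables[[nm]], phenotypes)
  all_feats <- feature_cols(tables[[1]])
  features <- features %||% all_feats
  unknown <- setdiff(features, all_feats)
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown feature(s): ", toString(unknown),
      ". Valid features include: ", toString(head(all_feats, 10)),
      if (length(all_feats) > 10) ", ..." else "", "."
    ))
  }
  is_control <- phenotypes$diagnosis == "control"
  grid <- tidyr::expand_grid(feature = features, method = names(tables))
  out <- purrr::pmap_dfr(grid, function(feature, method) {
    y <- tables[[method]][[feature]]
    tibble::tibble(
      feature = feature, method = method,
      n_control = sum(is_control), n_patient = sum(!is_control),
      g = hedges_g(y[is_control], y[!is_control], correct_bias = correct_bias)
    )
  })
  if ("original" %in% names(tables)) {
    orig <- out[out$method == "original", c("feature", "g")]
    names(orig)[2] <- ".g_original"
    out <- dplyr::left_join(out, orig, by = "feature")
    out$percent_change <- percent_change(out$g, out$.g_original)
    out$.g_original <- NULL
  } else {
    out$percent_change <- NA_real_
  }
  out$method <- factor(out$method, levels = names(tables))
  out
}

#' Published multi-site case-control effect sizes
#'
#' Reported Hedges' g values for the canonical resting-state FC features of
#' the B-SNIP schizophrenia and ABIDE autism cohorts, for the original data
#' and the three site-effect mitigation methods. Useful for demonstrating
#' the percent-change convention without access to the raw imaging data.
#'
#' @return A tibble with columns `study`, `contrast`, `feature`, and the
#'   reported g values `original`, `glm`, `combat`, `swd`.
#' @export
reference_effect_sizes <- function() {
  tibble::tribble(
    ~study,   ~contrast,    ~feature,              ~original, ~glm,   ~combat, ~swd,
    "B-SNIP", "SZ vs HC",   "within MPFC",         0.3069,    0.1761, 0.2379,  0.3206,
    "B-SNIP", "SZ vs HC",   "MPFC-ACC",            0.2046,    0.1228, 0.1557,  0.2207,
    "ABIDE",  "ASD vs HC",  "MPFC-PCC/precuneus",  0.2634,    0.2436, 0.2769,  0.2773,
    "ABIDE",  "ASD vs HC",  "MPFC-MTG",            0.4892,    0.4334, 0.4829,  0.5034
  )
}
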