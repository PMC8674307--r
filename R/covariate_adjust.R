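# Build a design matrix from phenotypes. Site enters as reference-coded
# indicators (first level is the reference); rank is checked after encoding.
build_design <- function(phenotypes, terms = c("age", "sex"),
                         intercept = TRUE) {
  n <- nrow(phenotypes)
  cols <- list()
  if (intercept) cols[["(Intercept)"]] <- rep(1, n)
  for (t in terms) {
    if (t == "site") {
      site <- droplevels(factor(phenotypes$site))
      lev <- levels(site)
      if (length(lev) > 1) {
        for (l in lev[-1]) cols[[paste0("site", l)]] <- as.numeric(site == l)
      }
    } else if (t == "diagnosis") {
      cols[["diagnosis"]] <- as.numeric(phenotypes$diagnosis == "patient")
    } else {
      if (!t %in% names(phenotypes)) {
        abort(sprintf("Covariate '%s' not found in phenotype table.", t))
      }
      cols[[t]] <- as.numeric(phenotypes[[t]])
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (ncol(X) == 0) return(X)
  if (qr(X)$rank < ncol(X)) {
    abort(paste0(
      "Design matrix is rank deficient (columns: ", toString(colnames(X)),
      "); check for constant or confounded covariates."
    ))
  }
  X
}

# lm.fit drops matrix structure for a single response; keep it
ols_fit <- function(X, Y) {
  fit <- lm.fit(X, Y)
  coef <- fit$coefficients
  res <- fit$residuals
  if (is.null(dim(coef))) {
    coef <- matrix(coef, ncol = 1, dimnames = list(names(coef), colnames(Y)))
    res <- matrix(res, ncol = 1, dimnames = dimnames(Y))
  }
  list(coefficients = coef, residuals = res)
}

#' Regress nuisance covariates out of every FC feature
#'
#' Fits `feature ~ intercept + covariates` by ordinary least squares, one fit
#' per feature, and returns the residuals. By default the fitted intercept is
#' added back so harmonized values keep their physical level (grand-mean
#' centering would strip the features of their original scale); residuals
#' remain exactly orthogonal to the covariates either way. The operation is
#' idempotent.
#'
#' @param features Feature table (subjects x features).
#' @param phenotypes Phenotype table aligned row-for-row with `features`.
#' @param covariates Phenotype columns to remove (default age and sex; linear
#'   terms only).
#' @param keep_level Add the fitted intercept back to the residuals
#'   (default `TRUE`). Set `FALSE` for pure residuals.
#' @return Feature table of residuals with provenance step `"residualized"`.
#' @export
residualize_covariates <- function(features, phenotypes,
                                   covariates = c("age", "sex"),
                                   keep_level = TRUE) {
  check_feature_table(features)
  check_aligned(features, phenotypes)
  Y <- fc_values(features)
  X <- build_design(phenotypes, terms = covariates, intercept = TRUE)
  if (nrow(X) <= ncol(X)) {
    abort(sprintf("Need more subjects (%d) than design columns (%d).",
                  nrow(X), ncol(X)))
  }
  fit <- ols_fit(X, Y)
  res <- fit$residuals
  if (keep_level) {
    res <- sweep(res, 2, fit$coefficients["(Intercept)", ], `+`)
  }
  dimnames(res) <- dimnames(Y)
  fc_rebuild(features, res, add_step = "residualized")
}
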