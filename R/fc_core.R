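#' Pearson functional-connectivity matrix of a regional time series
#'
#' Correlates every pair of regional time courses, giving the symmetric
#' R x R FC matrix with a unit diagonal.
#'
#' @param ts An [roi_timeseries()] object, or a numeric T x R matrix.
#' @return Numeric R x R correlation matrix with region labels as dimnames.
#' @export
compute_fc <- function(ts) {
  values <- if (inherits(ts, "roi_ts")) ts$values else as.matrix(ts)
  if (nrow(values) < 3) {
    abort("Pearson FC needs >= 3 timepoints to be non-degenerate.")
  }
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(values)[sds == 0] %||% which(sds == 0)
    abort(paste0("Zero-variance region(s), correlation undefined: ",
                 toString(head(bad, 5)), "."))
  }
  m <- stats::cor(values)
  # enforce exact symmetry and unit diagonal against rounding
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = atanh(r)`, the variance-stabilizing transform applied to every FC
#' value before harmonization. Correlations at the boundary (|r| = 1) are
#' clipped to `1 - clip_eps` so the transform stays finite; boundary values
#' cannot occur off-diagonal in real data but do occur in toy inputs.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @param clip_eps Positive clipping distance from |r| = 1 (default `1e-7`).
#' @return `atanh()` of the clipped input, same shape as `r`.
#' @export
fisher_z <- function(r, clip_eps = 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    abort(sprintf("|r| > 1 is not a correlation (max |r| = %.6g).",
                  max(abs(r), na.rm = TRUE)))
  }
  if (clip_eps <= 0) abort("`clip_eps` must be positive.")
  atanh(pmin(pmax(r, -1 + clip_eps), 1 - clip_eps))
}

#' Vectorize an FC matrix to its upper-triangle feature row
#'
#' Extracts the strict upper triangle in the canonical row-major, 0-based
#' order of [feature_pairs()]; [devectorize_fc()] is the inverse, rebuilding
#' the symmetric matrix with a unit diagonal.
#'
#' @param fc Symmetric R x R FC matrix.
#' @return Named numeric vector of length `R(R-1)/2`.
#' @export
vectorize_fc <- function(fc) {
  fc <- as.matrix(fc)
  if (nrow(fc) != ncol(fc)) abort("FC matrix must be square.")
  # row-major upper triangle == column-major walk of the transposed lower tri
  v <- t(fc)[lower.tri(fc)]
  names(v) <- feature_pairs(nrow(fc))$feature
  v
}

#' @rdname vectorize_fc
#' @param values Feature row of length `R(R-1)/2`.
#' @param diag_value Value placed on the diagonal (default 1).
#' @export
devectorize_fc <- function(values, diag_value = 1) {
  n_regions <- n_regions_from_features(length(values))
  tm <- matrix(0, n_regions, n_regions)
  tm[lower.tri(tm)] <- values    # fills the transpose column-major
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_value
  m
}

#' Build a Fisher-z FC feature table from regional time series
#'
#' Runs [compute_fc()], [fisher_z()] and [vectorize_fc()] for each subject
#' and assembles the subjects x features tibble that all harmonizers consume,
#' aligned to the phenotype table's subject order.
#'
#' @param timeseries Named list of [roi_timeseries()] objects (names or
#'   `subject_id` fields give the subject IDs).
#' @param phenotypes Optional phenotype table; if given, rows are aligned to
#'   its subject order and missing subjects are an error.
#' @param clip_eps Passed to [fisher_z()].
#' @return Feature table with provenance `"fisher_z"`.
#' @export
fc_feature_table <- function(timeseries, phenotypes = NULL, clip_eps = 1e-7) {
  ids <- vapply(timeseries, function(t) t$subject_id, character(1))
  if (anyDuplicated(ids)) abort("Duplicated subject_id among time series.")
  names(timeseries) <- ids
  if (!is.null(phenotypes)) {
    missing <- setdiff(phenotypes$subject_id, ids)
    if (length(missing) > 0) {
      abort(paste0("Subjects in phenotype table without time series: ",
                   toString(head(missing, 10)), "."))
    }
    timeseries <- timeseries[as.character(phenotypes$subject_id)]
    ids <- names(timeseries)
  }
  rows <- purrr::map(timeseries, function(t) {
    fisher_z(vectorize_fc(compute_fc(t)), clip_eps = clip_eps)
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    abort("All subjects must have the same number of regions.")
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(tibble::tibble(subject_id = ids), out)
  fc_provenance(out) <- "fisher_z"
  out
}
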