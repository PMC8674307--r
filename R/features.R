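#' Upper-triangle feature index for an R-region connectivity matrix
#'
#' FC feature tables store the strict upper triangle of a symmetric
#' region-by-region matrix, row-major, 0-based, with `a < b`. The diagonal is
#' never stored (the Fisher z-transform of r = 1 is infinite). A matrix over
#' `n_regions` regions therefore yields `n_regions * (n_regions - 1) / 2`
#' features, named `"a_b"`.
#'
#' @param n_regions Number of regions (>= 2).
#' @return A tibble with columns `feature` (the `"a_b"` name), `a`, `b`
#'   (0-based region indices, `a < b`), in canonical row-major order.
#' @examples
#' feature_pairs(3) # features "0_1", "0_2", "1_2"
#' @export
feature_pairs <- function(n_regions) {
  if (!is.numeric(n_regions) || length(n_regions) != 1 || n_regions < 2) {
    abort("`n_regions` must be a single integer >= 2.")
  }
  n_regions <- as.integer(n_regions)
  a <- rep(0:(n_regions - 2L), times = (n_regions - 1L):1L)
  b <- unlist(lapply(0:(n_regions - 2L), function(i) (i + 1L):(n_regions - 1L)))
  tibble::tibble(feature = paste0(a, "_", b), a = a, b = b)
}

#' Map a 0-based region pair to its feature column position
#'
#' Inverse of the row-major upper-triangle ordering of [feature_pairs()].
#'
#' @param a,b 0-based region indices with `a < b` (vectorized).
#' @param n_regions Number of regions.
#' @return 1-based position(s) of the pair among the
#'   `n_regions * (n_regions - 1) / 2` features.
#' @export
pair_index <- function(a, b, n_regions) {
  if (any(a >= b) || any(a < 0) || any(b >= n_regions)) {
    abort("Require 0 <= a < b < n_regions.")
  }
  as.integer(a * (n_regions - 1) - a * (a - 1) / 2 + (b - a))
}

n_regions_from_features <- function(n_features) {
  r <- (1 + sqrt(1 + 8 * n_features)) / 2
  if (abs(r - round(r)) > 1e-8) {
    abort(sprintf(
      "%d features do not form a full upper triangle (no integer R with R(R-1)/2 = %d).",
      n_features, n_features
    ))
  }
  as.integer(round(r))
}

# ---- feature-table helpers -------------------------------------------------

feature_cols <- function(features) {
  setdiff(names(features), "subject_id")
}

#' Extract the numeric value matrix of an FC feature table
#'
#' @param features A feature table: a tibble whose first column is
#'   `subject_id` and whose remaining columns are numeric FC features.
#' @return A numeric matrix (subjects x features) with subject IDs as row
#'   names.
#' @export
fc_values <- function(features) {
  check_feature_table(features)
  m <- as.matrix(features[feature_cols(features)])
  rownames(m) <- features$subject_id
  m
}

# replace the numeric block, keeping subject_id, names and provenance
fc_rebuild <- function(features, values, add_step = NULL) {
  stopifnot(nrow(values) == nrow(features))
  out <- features
  out[feature_cols(features)] <- as.data.frame(values)
  prov <- fc_provenance(features)
  if (!is.null(add_step)) prov <- c(prov, add_step)
  fc_provenance(out) <- prov
  out
}

check_feature_table <- function(features) {
  if (!is.data.frame(features) || !"subject_id" %in% names(features)) {
    abort("A feature table must be a data frame with a `subject_id` column.")
  }
  vals <- features[feature_cols(features)]
  if (ncol(vals) == 0) abort("Feature table has no feature columns.")
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Non-numeric feature columns: ", toString(head(bad, 5)), "."))
  }
  if (anyDuplicated(features$subject_id)) {
    dup <- unique(features$subject_id[duplicated(features$subject_id)])
    abort(paste0("Duplicated subject_id in feature table: ", toString(head(dup, 5)), "."))
  }
  invisible(features)
}

check_aligned <- function(features, phenotypes) {
  if (!identical(as.character(features$subject_id),
                 as.character(phenotypes$subject_id))) {
    abort(paste0(
      "Feature table and phenotype table are not aligned: subject_id columns ",
      "must be identical and in the same order."
    ))
  }
  invisible(TRUE)
}

# ---- provenance ------------------------------------------------------------

#' Transform provenance of a feature table
#'
#' Every transform in this package appends its name to an ordered provenance
#' list carried as an attribute (and serialized as a header comment by
#' [write_feature_table()]). The pipeline uses it to enforce the canonical
#' order fisher_z -> residualized -> harmonization and to refuse to
#' double-apply a harmonizer.
#'
#' @param features A feature table.
#' @param value Character vector of transform names.
#' @return `fc_provenance()` returns a character vector (possibly empty).
#' @export
fc_provenance <- function(features) {
  as.character(attr(features, "fc_provenance") %||% character(0))
}

#' @rdname fc_provenance
#' @export
`fc_provenance<-` <- function(features, value) {
  attr(features, "fc_provenance") <- as.character(value)
  features
}
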