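delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = ",",
    tsv = "\t",
    abort(sprintf("Unsupported file extension '.%s' (use .csv or .tsv): %s", ext, path))
  )
}

#' Read a phenotype table
#'
#' Reads a delimited (.csv or .tsv) per-subject phenotype table with subject
#' ID, acquisition site, diagnosis, age and sex, and coerces it to the
#' canonical coding used throughout the package: diagnosis as a factor with
#' levels `control`, `patient`; sex as 0 = male, 1 = female; site as a factor
#' over the observed (or declared) site labels.
#'
#' @param path Path to a `.csv` or `.tsv` file with a header.
#' @param columns Named character vector mapping the canonical column names
#'   (`subject_id`, `site`, `diagnosis`, `age`, `sex`) to the names used in
#'   the file.
#' @param control_label,patient_label Diagnosis labels in the file mapped to
#'   `control` / `patient` (case-insensitive). Any other label is an error.
#' @param sites Optional character vector declaring the full site set; site
#'   labels outside it are an error.
#' @return A tibble with columns `subject_id`, `site`, `diagnosis`, `age`,
#'   `sex`.
#' @export
read_phenotypes <- function(path,
                            columns = c(subject_id = "subject_id", site = "site",
                                        diagnosis = "diagnosis", age = "age",
                                        sex = "sex"),
                            control_label = "control",
                            patient_label = "patient",
                            sites = NULL) {
  needed <- c("subject_id", "site", "diagnosis", "age", "sex")
  if (!all(needed %in% names(columns))) {
    abort(paste0("`columns` must name all of: ", toString(needed), "."))
  }
  raw <- readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(unname(columns[needed]), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Phenotype file is missing columns: ", toString(missing_cols), "."))
  }
  ph <- tibble::tibble(
    subject_id = raw[[columns[["subject_id"]]]],
    site       = raw[[columns[["site"]]]],
    diagnosis  = raw[[columns[["diagnosis"]]]],
    age        = raw[[columns[["age"]]]],
    sex        = raw[[columns[["sex"]]]]
  )
  dup <- unique(ph$subject_id[duplicated(ph$subject_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicated subject_id in phenotype table: ", toString(head(dup, 5)), "."))
  }

  dx <- tolower(trimws(ph$diagnosis))
  dx_out <- rep(NA_character_, length(dx))
  dx_out[dx == tolower(control_label)] <- "control"
  dx_out[dx == tolower(patient_label)] <- "patient"
  if (anyNA(dx_out)) {
    i <- which(is.na(dx_out))[1]
    abort(sprintf(
      "Unknown diagnosis label '%s' for subject '%s' (row %d); expected '%s' or '%s'.",
      ph$diagnosis[i], ph$subject_id[i], i, control_label, patient_label
    ))
  }

  sx <- tolower(trimws(ph$sex))
  sx_out <- rep(NA_integer_, length(sx))
  sx_out[sx %in% c("0", "m", "male")] <- 0L
  sx_out[sx %in% c("1", "f", "female")] <- 1L
  if (anyNA(ph$sex) || any(sx == "")) {
    i <- which(is.na(ph$sex) | sx == "")[1]
    abort(sprintf("Missing sex for subject '%s' (row %d).", ph$subject_id[i], i))
  }
  if (anyNA(sx_out)) {
    i <- which(is.na(sx_out))[1]
    abort(sprintf("Unrecognized sex value '%s' for subject '%s' (row %d).",
                  ph$sex[i], ph$subject_id[i], i))
  }

  age <- suppressWarnings(as.numeric(ph$age))
  if (anyNA(age)) {
    i <- which(is.na(age))[1]
    abort(sprintf("Missing or non-numeric age '%s' for subject '%s' (row %d).",
                  as.character(ph$age[i]), ph$subject_id[i], i))
  }

  site_levels <- sites %||% unique(ph$site)
  unknown <- setdiff(unique(ph$site), site_levels)
  if (length(unknown) > 0) {
    abort(paste0("Site labels outside the declared set: ", toString(unknown), "."))
  }

  tibble::tibble(
    subject_id = ph$subject_id,
    site = factor(ph$site, levels = site_levels),
    diagnosis = factor(dx_out, levels = c("control", "patient")),
    age = age,
    sex = sx_out
  )
}

#' Construct a regional time-series object
#'
#' @param values Numeric T x R matrix (timepoints by regions).
#' @param subject_id Subject identifier.
#' @param region_labels Optional region labels (defaults to `"r1"..."rR"`).
#' @return An object of class `roi_ts`.
#' @export
roi_timeseries <- function(values, subject_id = "subject",
                           region_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("Time-series values must be numeric.")
  if (nrow(values) < 2) {
    abort("A time series needs at least 2 timepoints.")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-finite time-series value at timepoint %d, region %d.",
                  idx[1], idx[2]))
  }
  region_labels <- region_labels %||% paste0("r", seq_len(ncol(values)))
  if (length(region_labels) != ncol(values)) {
    abort("`region_labels` length must equal the number of regions.")
  }
  colnames(values) <- region_labels
  structure(list(subject_id = subject_id, values = values,
                 region_labels = region_labels),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject '%s': %d timepoints x %d regions\n",
              x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read one subject's regional time series
#'
#' Expects a `.csv`/`.tsv` numeric matrix, timepoints in rows and regions in
#' columns, with an optional header row of region labels.
#'
#' @param path Path to the file.
#' @param subject_id Subject ID; defaults to the file name without extension.
#' @return An `roi_ts` object (see [roi_timeseries()]).
#' @export
read_timeseries <- function(path, subject_id = NULL) {
  subject_id <- subject_id %||% tools::file_path_sans_ext(basename(path))
  delim <- delim_for(path)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("Empty time-series file: ", path))
  split1 <- strsplit(lines[1], delim, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(split1)))
  labels <- if (has_header) trimws(split1) else NULL
  body <- if (has_header) lines[-1] else lines
  cells <- strsplit(body, delim, fixed = TRUE)
  ncols <- length(split1)
  vals <- suppressWarnings(
    t(vapply(cells, function(x) as.numeric(x)[seq_len(ncols)], numeric(ncols)))
  )
  if (ncols == 1) vals <- matrix(unlist(vals), ncol = 1)
  if (nrow(vals) < 3) {
    abort(sprintf(
      "Time-series file has %d timepoint(s); Pearson FC needs >= 3: %s",
      nrow(vals), path
    ))
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    raw <- cells[[idx[1]]][idx[2]]
    abort(sprintf("Non-numeric value '%s' at row %d, column %d of %s.",
                  if (is.na(raw)) "" else raw,
                  idx[1] + has_header, idx[2], path))
  }
  roi_timeseries(vals, subject_id = subject_id, region_labels = labels)
}

#' Write / read an FC feature table
#'
#' Feature tables are written as delimited text with a `subject_id` first
#' column, `"a_b"` feature headers, and a leading `# provenance:` comment
#' recording the ordered transforms applied. The round trip is lossless to
#' full double precision.
#'
#' @param features Feature table (tibble with `subject_id` + numeric columns).
#' @param path Output `.csv` or `.tsv` path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the feature table with its provenance
#'   attribute restored.
#' @export
write_feature_table <- function(features, path) {
  check_feature_table(features)
  delim <- delim_for(path)
  prov <- fc_provenance(features)
  header <- paste0("# provenance: ", paste(prov, collapse = ","))
  readr::write_lines(header, path)
  readr::write_delim(features, path, delim = delim, append = TRUE,
                     col_names = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param phenotypes Optional phenotype table; if supplied, the subject order
#'   must match exactly or an error is raised.
#' @export
read_feature_table <- function(path, phenotypes = NULL) {
  first <- readr::read_lines(path, n_max = 1)
  prov <- character(0)
  if (length(first) == 1 && grepl("^# provenance:", first)) {
    body <- trimws(sub("^# provenance:", "", first))
    if (nzchar(body)) prov <- trimws(strsplit(body, ",", fixed = TRUE)[[1]])
  }
  tbl <- readr::read_delim(path, delim = delim_for(path), comment = "#",
                           show_col_types = FALSE,
                           col_types = readr::cols(
                             subject_id = readr::col_character(),
                             .default = readr::col_double()
                           ))
  tbl <- tibble::as_tibble(tbl)
  check_feature_table(tbl)
  fc_provenance(tbl) <- prov
  if (!is.null(phenotypes)) check_aligned(tbl, phenotypes)
  tbl
}
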