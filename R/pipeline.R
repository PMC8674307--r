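harmonization_steps <- c("swd", "glm_full", "glm_site", "combat")

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Read every subject's time series from a directory
#'
#' Looks for `<subject_id>.csv` or `<subject_id>.tsv` for each phenotype row;
#' subjects without a file are reported together in one error.
#'
#' @param dir Directory of per-subject time-series files.
#' @param phenotypes Phenotype table defining the subject set and order.
#' @return Named list of [roi_timeseries()] objects in phenotype order.
#' @export
read_timeseries_dir <- function(dir, phenotypes) {
  ids <- as.character(phenotypes$subject_id)
  paths <- vapply(ids, function(id) {
    for (ext in c(".csv", ".tsv")) {
      p <- file.path(dir, paste0(id, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }, character(1))
  if (anyNA(paths)) {
    abort(paste0("No time-series file for subject(s): ",
                 toString(head(ids[is.na(paths)], 10)), " in ", dir, "."))
  }
  out <- lapply(seq_along(ids), function(k) read_timeseries(paths[k], subject_id = ids[k]))
  names(out) <- ids
  out
}

#' Run the full harmonization and effect-size pipeline
#'
#' Orchestrates the canonical workflow: (time series ->) Pearson FC ->
#' Fisher z -> age/sex residualization ("original") -> each requested
#' harmonizer -> per-feature Hedges' g report with percent changes. SWD is
#' applied to the residualized table; GLM and ComBat are applied to the
#' Fisher-z table with their own covariate designs, and the ComBat output
#' then has age and sex regressed out, so each method sees the inputs its
#' model expects. Provenance is checked so a table that is not on the
#' Fisher-z scale, or has already been harmonized, is refused unless
#' `force = TRUE`.
#'
#' @param phenotypes Phenotype table.
#' @param features Fisher-z feature table aligned with `phenotypes`
#'   (omit when `timeseries` is given).
#' @param timeseries Named list of [roi_timeseries()] objects, or a directory
#'   path of per-subject files.
#' @param methods Subset of `c("swd", "glm", "combat")`.
#' @param features_of_interest Feature names for the report (`NULL` = all).
#' @param glm_mode Passed to [harmonize_glm()].
#' @param correct_bias Passed to [hedges_g()].
#' @param clip_eps Passed to [fisher_z()].
#' @param out_dir If non-`NULL`, write per-method feature tables, parameter
#'   sidecars, and the report as CSV there.
#' @param force Skip provenance checks.
#' @param verbose Log one line per stage.
#' @return An `fc_pipeline` list: `report` (tibble), `tables` (named list of
#'   feature tables incl. `original`), `harmony` (named list of `fc_harmony`
#'   objects).
#' @export
run_pipeline <- function(phenotypes, features = NULL, timeseries = NULL,
                         methods = c("swd", "glm", "combat"),
                         features_of_interest = NULL,
                         glm_mode = c("full", "site-only"),
                         correct_bias = FALSE, clip_eps = 1e-7,
                         out_dir = NULL, force = FALSE, verbose = TRUE) {
  glm_mode <- match.arg(glm_mode)
  bad <- setdiff(methods, c("swd", "glm", "combat"))
  if (length(bad) > 0) {
    abort(paste0("Unknown method(s): ", toString(bad),
                 "; choose from swd, glm, combat."))
  }

  if (!is.null(timeseries)) {
    if (is.character(timeseries) && length(timeseries) == 1) {
      timeseries <- read_timeseries_dir(timeseries, phenotypes)
    }
    features <- fc_feature_table(timeseries, phenotypes, clip_eps = clip_eps)
    stage_log(verbose, "fc", "computed FC for %d subjects, %d features",
              nrow(features), length(feature_cols(features)))
  }
  if (is.null(features)) {
    abort("Provide either `features` or `timeseries`.")
  }
  check_aligned(features, phenotypes)

  prov <- fc_provenance(features)
  if (!force) {
    if (!"fisher_z" %in% prov) {
      abort(paste0(
        "Feature table provenance lacks 'fisher_z' (found: ",
        if (length(prov)) toString(prov) else "none",
        "); harmonizers expect Fisher-z values. Use force = TRUE to override."
      ))
    }
    applied <- intersect(harmonization_steps, prov)
    if (length(applied) > 0) {
      abort(paste0("Table was already harmonized (", toString(applied),
                   "); refusing to re-harmonize. Use force = TRUE to override."))
    }
  }

  if ("residualized" %in% prov) {
    original <- features
  } else {
    original <- residualize_covariates(features, phenotypes)
    stage_log(verbose, "adjust", "residualized age + sex over %d features",
              length(feature_cols(original)))
  }

  harmony <- list()
  tables <- list(original = original)
  for (m in methods) {
    h <- switch(m,
      swd = harmonize_swd(original, phenotypes),
      glm = harmonize_glm(features, phenotypes, mode = glm_mode),
      combat = harmonize_combat(features, phenotypes, adjust_covariates = TRUE)
    )
    harmony[[m]] <- h
    tables[[m]] <- h$table
    stage_log(verbose, m, "harmonized %d x %d table (provenance: %s)",
              nrow(h$table), length(feature_cols(h$table)),
              paste(fc_provenance(h$table), collapse = " -> "))
  }

  report <- feature_effect(tables, phenotypes,
                           features = features_of_interest,
                           correct_bias = correct_bias)
  stage_log(verbose, "effectsize", "report: %d features x %d methods",
            length(unique(report$feature)), length(unique(report$method)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      write_feature_table(tables[[nm]], file.path(out_dir, paste0("features_", nm, ".csv")))
    }
    for (nm in names(harmony)) {
      readr::write_csv(tidy(harmony[[nm]]),
                       file.path(out_dir, paste0("parameters_", nm, ".csv")))
    }
    report_out <- report
    report_out$percent_change <- round_half_away(report_out$percent_change, 1)
    readr::write_csv(report_out, file.path(out_dir, "report.csv"))
    stage_log(verbose, "write", "outputs in %s", out_dir)
  }

  structure(list(report = report, tables = tables, harmony = harmony),
            class = "fc_pipeline")
}

#' @export
print.fc_pipeline <- function(x, ...) {
  cat(sprintf("<fc_pipeline> methods: %s\n",
              toString(setdiff(names(x$tables), "original"))))
  print(x$report, n = 20)
  invisible(x)
}

#' Run the pipeline from a YAML configuration file
#'
#' Keys: `phenotypes` (path), one of `features` (path) or `timeseries_dir`,
#' and optionally `methods`, `features_of_interest`, `glm_mode`,
#' `correct_bias`, `clip_eps`, `out_dir`, `force`.
#'
#' @param config_path Path to a YAML file.
#' @param verbose Log stage lines.
#' @return See [run_pipeline()].
#' @export
run_pipeline_file <- function(config_path, verbose = TRUE) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$phenotypes)) abort("Config must name a `phenotypes` file.")
  for (key in c("phenotypes", "features")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      abort(sprintf("Configured %s path does not exist: %s", key, cfg[[key]]))
    }
  }
  phen <- read_phenotypes(cfg$phenotypes)
  features <- if (!is.null(cfg$features)) read_feature_table(cfg$features, phen)
  run_pipeline(
    phenotypes = phen,
    features = features,
    timeseries = cfg$timeseries_dir,
    methods = cfg$methods %||% c("swd", "glm", "combat"),
    features_of_interest = cfg$features_of_interest,
    glm_mode = cfg$glm_mode %||% "full",
    correct_bias = isTRUE(cfg$correct_bias),
    clip_eps = cfg$clip_eps %||% 1e-7,
    out_dir = cfg$out_dir,
    force = isTRUE(cfg$force),
    verbose = verbose
  )
}
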