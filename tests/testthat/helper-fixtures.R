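# deterministic toy cohort builders used across the suite

toy_phenotypes <- function(n = 6, sites = rep(c("A", "B"), each = n / 2),
                           diagnosis = rep(c("control", "patient"), n / 2),
                           age = seq(20, 20 + n - 1),
                           sex = rep(c(0L, 1L), length.out = n)) {
  tibble::tibble(
    subject_id = sprintf("sub-%02d", seq_len(n)),
    site = factor(sites),
    diagnosis = factor(diagnosis, levels = c("control", "patient")),
    age = as.numeric(age), sex = as.integer(sex)
  )
}

toy_features <- function(values, phenotypes,
                         provenance = c("fisher_z", "residualized")) {
  values <- as.matrix(values)
  colnames(values) <- colnames(values) %||% paste0("f", seq_len(ncol(values)))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = phenotypes$subject_id),
    tibble::as_tibble(values)
  )
  fc_provenance(out) <- provenance
  out
}

random_features <- function(phenotypes, n_features = 8, seed = 1,
                            provenance = c("fisher_z", "residualized")) {
  set.seed(seed)
  toy_features(matrix(rnorm(nrow(phenotypes) * n_features, 0.2, 0.3),
                      nrow(phenotypes), n_features),
               phenotypes, provenance = provenance)
}

write_phenotype_csv <- function(df, path = withr::local_tempfile(fileext = ".csv",
                                                                 .local_envir = parent.frame())) {
  readr::write_csv(df, path)
  path
}

`%||%` <- rlang::`%||%`
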