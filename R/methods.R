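#' Tidy the estimated parameters of a harmonization result
#'
#' Returns the method's estimates in long form: the per-site scalar means
#' for SWD; per-feature regression coefficients for GLM; per-site,
#' per-feature raw and EB-shrunk location/scale estimates for ComBat.
#'
#' @param x An `fc_harmony` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fc_harmony <- function(x, ...) {
  switch(x$method,
    swd = dplyr::mutate(x$parameters$site_means, term = "site_mean",
                        .before = 1),
    glm = tidyr::pivot_longer(x$parameters$coefficients, -"feature",
                              names_to = "term", values_to = "estimate"),
    combat = {
      long <- function(m, nm) {
        tibble::as_tibble(m, rownames = "site") |>
          tidyr::pivot_longer(-"site", names_to = "feature", values_to = nm)
      }
      long(x$parameters$gamma_hat, "gamma_hat") |>
        dplyr::inner_join(long(x$parameters$gamma_star, "gamma_star"),
                          by = c("site", "feature")) |>
        dplyr::inner_join(long(x$parameters$delta2_hat, "delta2_hat"),
                          by = c("site", "feature")) |>
        dplyr::inner_join(long(x$parameters$delta2_star, "delta2_star"),
                          by = c("site", "feature"))
    }
  )
}

#' One-row summary of a harmonization result
#'
#' @param x An `fc_harmony` object.
#' @param ... Unused.
#' @return A tibble with the method, table dimensions, number of sites, and
#'   (for ComBat) the total EB iteration count.
#' @export
glance.fc_harmony <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_subjects = nrow(x$table),
    n_features = length(feature_cols(x$table)),
    n_sites = switch(x$method,
      swd = nrow(x$parameters$site_means),
      combat = nrow(x$parameters$hyper),
      glm = sum(grepl("^site", x$details$design_columns)) + 1L
    ),
    iterations = if (x$method == "combat") sum(x$parameters$hyper$iterations)
                 else NA_integer_
  )
}

#' Plot a harmonization result's site parameters
#'
#' SWD: the per-site scalar means. GLM: distributions of the per-feature
#' site-indicator coefficients. ComBat: raw vs EB-shrunk per-feature site
#' location effects, showing the shrinkage toward each site's prior mean.
#'
#' @param object An `fc_harmony` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_harmony <- function(object, ...) {
  td <- tidy(object)
  switch(object$method,
    swd = ggplot2::ggplot(td, ggplot2::aes(x = .data$site, y = .data$mean)) +
      ggplot2::geom_col() +
      ggplot2::labs(y = "site-wise FC mean (Fisher z)",
                    title = "SWD per-site scalar means"),
    glm = ggplot2::ggplot(
        dplyr::filter(td, grepl("^site", .data$term)),
        ggplot2::aes(x = .data$estimate, fill = .data$term)
      ) +
      ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
      ggplot2::labs(x = "site coefficient (Fisher z)",
                    title = "GLM per-feature site-indicator estimates"),
    combat = ggplot2::ggplot(
        td, ggplot2::aes(x = .data$gamma_hat, y = .data$gamma_star,
                         colour = .data$site)
      ) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::labs(x = "raw site location (standardized)",
                    y = "EB-shrunk site location",
                    title = "ComBat empirical-Bayes shrinkage")
  )
}

#' Bar chart of an effect-size report
#'
#' @param report Output of [feature_effect()].
#' @return A ggplot object: Hedges' g per feature and method.
#' @export
plot_effect_sizes <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$feature, y = .data$g,
                               fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(y = "Hedges' g (control - patient)",
                  title = "Case-control effect size by harmonization method")
}
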