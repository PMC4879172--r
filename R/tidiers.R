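#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained classifier into its importance table
#'
#' @param x A `pollen_classifier`.
#' @param ... Unused.
#' @return A tibble (`term`, `importance`, `rank`) in descending order of
#'   permutation importance.
#' @method tidy pollen_classifier
#' @export
tidy.pollen_classifier <- function(x, ...) x$importance

#' One-row summary of a trained classifier
#'
#' @param x A `pollen_classifier`.
#' @param ... Unused.
#' @return A tibble: `ntree`, `mtry`, `threshold`, `oof_distance`,
#'   `n_predictors`, `n_train`.
#' @method glance pollen_classifier
#' @export
glance.pollen_classifier <- function(x, ...) {
  tibble::tibble(ntree = x$spec$ntree, mtry = x$mtry,
                 threshold = x$threshold_star, oof_distance = x$oof_distance,
                 n_predictors = length(x$predictors), n_train = x$n_train)
}

#' Tidy an evaluation into one row of counts and metrics
#'
#' @param x A `model_evaluation`.
#' @param ... Unused.
#' @return A one-row tibble of metrics and confusion counts.
#' @method tidy model_evaluation
#' @export
tidy.model_evaluation <- function(x, ...) x$metrics

#' Tidy a confusion matrix into long form
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A tibble (`cell`, `count`).
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)),
                      dplyr::everything(),
                      names_to = "cell", values_to = "count")
}

#' Threshold-tuning curves of a trained classifier
#'
#' Resampled sensitivity, specificity, PPV, NPV and the distance to perfect
#' performance against the candidate probability cutoffs, with the
#' optimized cutoff marked.
#'
#' @param object A `pollen_classifier`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pollen_classifier
#' @export
autoplot.pollen_classifier <- function(object, ...) {
  prof <- tidyr::pivot_longer(object$resample_profile,
                              cols = c("sens", "spec", "ppv", "npv",
                                       "distance"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$threshold_star,
                        linetype = "dashed") +
    ggplot2::labs(x = "probability threshold", y = NULL,
                  title = "Resampled metrics over candidate thresholds") +
    ggplot2::theme_minimal()
}

#' Map view of a prediction raster
#'
#' Probability of a high pollen concentration level per grid cell,
#' facetted by date; masked cells are blank.
#'
#' @param object A `prediction_raster`.
#' @param layer `"probability"` or `"level"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prediction_raster
#' @export
autoplot.prediction_raster <- function(object,
                                       layer = c("probability", "level"),
                                       ...) {
  layer <- match.arg(layer)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       fill = .data[[layer]])) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~date) +
    ggplot2::coord_fixed(1.6) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot observed probability profiles of the top predictors
#'
#' @param model A `pollen_classifier`.
#' @param features A feature table to profile over.
#' @param predictors Predictors to show; default the four most important.
#' @param bins Bins per profile.
#' @return A ggplot of [probability_profile()] curves.
#' @export
plot_probability_profiles <- function(model, features, predictors = NULL,
                                      bins = 50) {
  predictors <- predictors %||% utils::head(model$importance$term, 4)
  curves <- purrr::map_dfr(predictors, function(p) {
    dplyr::mutate(probability_profile(model, features, p, bins), term = p)
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$bin_center,
                                       y = .data$mean_prob)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "predictor value",
                  y = "mean predicted probability of high level") +
    ggplot2::theme_minimal()
}
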