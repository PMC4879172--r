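#' Predict high-level probability for every grid cell
#'
#' Assembles the 30 predictors for each grid cell on the requested dates
#' (requiring a complete preceding year for the monthly temperature
#' features and a January 1 start for GDD accumulation), predicts the
#' probability of a high pollen concentration level, and applies the
#' model's optimized cutoff. Cells whose predictors cannot be computed for
#' a date are masked as no-data rather than dropped, so the raster geometry
#' is preserved.
#'
#' @param model A `pollen_classifier`.
#' @param met A met grid table (see [assemble_features()]).
#' @param dates Dates to predict (non-empty).
#' @param tbase GDD base temperature (degrees C).
#' @return A tibble of class `prediction_raster`: one row per cell and
#'   date with `cell`, `cell_x`, `cell_y`, `lon`, `lat`, `date`,
#'   `probability`, `level`, `masked`.
#' @export
predict_grid <- function(model, met, dates, tbase = 5) {
  dates <- as.Date(dates)
  if (length(dates) == 0) stop("no dates requested", call. = FALSE)
  feats <- assemble_features(met, locations = NULL, tbase = tbase,
                             drop_incomplete = FALSE)
  complete <- stats::complete.cases(feats[, model$predictors])
  valid_dates <- sort(unique(feats$date[complete]))
  if (length(valid_dates) == 0) {
    stop("no date has complete predictors in this met table", call. = FALSE)
  }
  bad <- dates < min(valid_dates)
  if (any(bad)) {
    stop("requested date(s) before feature availability; earliest valid ",
         "date is ", format(min(valid_dates)), call. = FALSE)
  }
  feats <- feats[feats$date %in% dates, ]
  complete <- stats::complete.cases(feats[, model$predictors])

  prob <- rep(NA_real_, nrow(feats))
  if (any(complete)) {
    prob[complete] <- predict(model, feats[complete, ], type = "prob")
  }
  geom_cols <- intersect(c("cell", "cell_x", "cell_y", "lon", "lat"),
                         names(met))
  geom <- dplyr::distinct(met[, geom_cols])
  out <- tibble::tibble(location = feats$location, date = feats$date,
                        probability = prob,
                        level = factor(ifelse(prob >= model$threshold_star,
                                              "high", "low"),
                                       levels = c("low", "high")),
                        masked = !complete)
  out$cell <- as.integer(sub("^cell_", "", out$location))
  out$location <- NULL
  out <- dplyr::left_join(out, geom, by = "cell")
  out <- dplyr::select(out, dplyr::any_of(c("cell", "cell_x", "cell_y",
                                            "lon", "lat")),
                       "date", "probability", "level", "masked")
  class(out) <- c("prediction_raster", class(out))
  out
}

#' Write a prediction raster to a plain-text layer file
#'
#' Long-format CSV with one row per cell and date, lon/lat coordinates,
#' the probability and level layers, and the no-data mask; round-trips
#' losslessly through [read_prediction_raster()].
#'
#' @param raster A `prediction_raster`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prediction_raster <- function(raster, path) {
  stopifnot(inherits(raster, "prediction_raster"))
  df <- as.data.frame(raster)
  df$date <- format(df$date)
  df$level <- as.character(df$level)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a prediction raster written by [write_prediction_raster()]
#'
#' @param path File path.
#' @return A `prediction_raster` tibble.
#' @export
read_prediction_raster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df$level <- factor(df$level, levels = c("low", "high"))
  df$probability <- as.numeric(df$probability)
  df$masked <- as.logical(df$masked)
  out <- tibble::as_tibble(df)
  class(out) <- c("prediction_raster", class(out))
  out
}
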