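#' Names of the 30 model predictors
#'
#' Twelve preceding-year monthly mean temperatures, fourteen 1-day-lagged
#' 4-/16-day window means of the seven daily meteorological fields,
#' cumulative growing degree days lagged by one day, and the three static
#' grid-cell coordinates.
#'
#' @return Character vector of length 30.
#' @export
predictor_names <- function() {
  c(paste0("TAVG_", toupper(month.name), "_PREVYEAR"),
    as.vector(t(outer(c("TMAX", "TMIN", "VAPORPRESSURE", "WINDSPEED",
                        "PRECIPITATION", "EVAPORATION", "RADIATION"),
                      c(4, 16),
                      function(v, k) paste0(v, "_", k, "DAYS_AVG_1DAYLAG")))),
    "GDD_1DAYLAG", "LONGITUDE", "LATITUDE", "ALTITUDE")
}

# met variable -> predictor stem used in window means
.met_var_stems <- c(tmax = "TMAX", tmin = "TMIN", vap = "VAPORPRESSURE",
                    wind = "WINDSPEED", prec = "PRECIPITATION",
                    evap = "EVAPORATION", rad = "RADIATION")

#' Daily growing degree days
#'
#' Heat accumulation above a base temperature: `(tmax + tmin)/2 - tbase`,
#' clamped at zero. No degree days accumulate when the daily maximum does
#' not exceed the base temperature, and the clamp also zeroes days whose
#' mean falls below the base even though the maximum exceeds it.
#'
#' @param tmax,tmin Daily maximum and minimum temperature (degrees C).
#' @param tbase Base temperature (degrees C); 5 is the standard growth
#'   threshold for temperate tree species.
#' @return Daily GDD (degree days, >= 0), vectorized.
#' @examples
#' daily_gdd(15, 5)   # 5
#' daily_gdd(4, -2)   # 0: tmax below base
#' daily_gdd(6, -10)  # 0: mean below base, clamped
#' @export
daily_gdd <- function(tmax, tmin, tbase = 5) {
  if (any(tmax < tmin, na.rm = TRUE)) {
    stop("tmax < tmin: invalid temperature pair", call. = FALSE)
  }
  gdd <- pmax(0, (tmax + tmin) / 2 - tbase)
  gdd[tmax <= tbase] <- 0
  gdd
}

#' Cumulative GDD lagged by one day
#'
#' Accumulates [daily_gdd()] from January 1 within each calendar year and
#' lags the running sum by one day, so the feature for day t is the heat
#' accumulated through day t-1; January 1 always maps to 0 and the sum
#' resets at every year boundary.
#'
#' @param dates Contiguous daily `Date` axis; each year must start Jan 1.
#' @param tmax,tmin Daily temperature extremes aligned with `dates`.
#' @inheritParams daily_gdd
#' @return Numeric vector of 1-day-lagged cumulative GDD.
#' @export
accumulate_gdd <- function(dates, tmax, tmin, tbase = 5) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(tmax), length(tmax) == length(tmin))
  if (length(dates) > 1 && any(diff(dates) != 1)) {
    stop("gap in daily time axis", call. = FALSE)
  }
  year <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  if (any(doy[!duplicated(year)] != 1L)) {
    stop("each year must start on January 1 for GDD accumulation", call. = FALSE)
  }
  gdd <- daily_gdd(tmax, tmin, tbase)
  cum <- stats::ave(gdd, year, FUN = cumsum)
  lagged <- dplyr::lag(cum)
  lagged[doy == 1L] <- 0
  lagged
}

#' Lagged rolling window mean
#'
#' The value at day t is the arithmetic mean of the k days strictly before t
#' (a k-day average lagged by one day). Days with fewer than k prior days
#' are missing; missing source values propagate.
#'
#' @param x Daily values.
#' @param k Window length in days (4 and 16 in the standard predictor set).
#' @return Numeric vector aligned with `x`.
#' @examples
#' rolling_mean_lagged(1:5, 4)  # NA NA NA NA 2.5
#' @export
rolling_mean_lagged <- function(x, k) {
  if (length(k) != 1 || is.na(k) || k != as.integer(k) || k < 1) {
    stop("k must be a positive integer", call. = FALSE)
  }
  dplyr::lag(zoo::rollmeanr(x, k, fill = NA))
}

#' Preceding-year monthly mean temperatures
#'
#' For a target year, the mean daily temperature (`(tmax + tmin)/2`) of each
#' month of the preceding calendar year. When the preceding year is not
#' fully present all twelve values are missing (rows for that year are
#' later excluded from modelling).
#'
#' @param dates Daily `Date` axis of one grid cell.
#' @param tmax,tmin Aligned daily temperature extremes.
#' @param year Target year; features describe `year - 1`.
#' @return Named numeric vector of length 12 (`TAVG_JANUARY_PREVYEAR`, ...).
#' @export
prevyear_monthly_tavg <- function(dates, tmax, tmin, year) {
  dates <- as.Date(dates)
  nm <- paste0("TAVG_", toupper(month.name), "_PREVYEAR")
  prev <- as.integer(format(dates, "%Y")) == year - 1
  n_expected <- as.integer(as.Date(paste0(year, "-01-01")) -
                             as.Date(paste0(year - 1, "-01-01")))
  if (sum(prev) < n_expected) {
    return(stats::setNames(rep(NA_real_, 12), nm))
  }
  tavg <- (tmax[prev] + tmin[prev]) / 2
  mo <- as.integer(format(dates[prev], "%m"))
  stats::setNames(as.numeric(tapply(tavg, factor(mo, levels = 1:12), mean)), nm)
}

# All 30 predictors for one cell's contiguous daily series.
cell_predictors <- function(cell_df, tbase = 5) {
  cell_df <- dplyr::arrange(cell_df, .data$date)
  if (nrow(cell_df) > 1 && any(diff(cell_df$date) != 1)) {
    stop("gap in daily time axis for cell ", cell_df$cell[1], call. = FALSE)
  }
  year <- as.integer(format(cell_df$date, "%Y"))
  doy <- as.integer(format(cell_df$date, "%j"))

  out <- tibble::tibble(cell = cell_df$cell, date = cell_df$date)
  # prev-year monthly means, constant within each target year
  tavg_by_year <- lapply(unique(year), function(y) {
    prevyear_monthly_tavg(cell_df$date, cell_df$tmax, cell_df$tmin, y)
  })
  tavg_mat <- do.call(rbind, tavg_by_year)[match(year, unique(year)), , drop = FALSE]
  out <- dplyr::bind_cols(out, tibble::as_tibble(tavg_mat))
  # lagged window means
  for (v in names(.met_var_stems)) {
    for (k in c(4L, 16L)) {
      out[[paste0(.met_var_stems[[v]], "_", k, "DAYS_AVG_1DAYLAG")]] <-
        rolling_mean_lagged(cell_df[[v]], k)
    }
  }
  # cumulative GDD needs full years from Jan 1; partial-start years are missing
  gddl <- rep(NA_real_, nrow(cell_df))
  for (y in unique(year)) {
    idx <- which(year == y)
    if (doy[idx[1]] == 1L) {
      gddl[idx] <- accumulate_gdd(cell_df$date[idx], cell_df$tmax[idx],
                                  cell_df$tmin[idx], tbase)
    }
  }
  out$GDD_1DAYLAG <- gddl
  out$LONGITUDE <- cell_df$lon
  out$LATITUDE <- cell_df$lat
  out$ALTITUDE <- cell_df$alt
  out
}

#' Match point locations to grid cells
#'
#' Nearest cell center by great-circle (haversine) distance, ties broken by
#' the lowest cell index. Locations falling outside the grid's bounding box
#' (padded by one cell spacing) are rejected by name.
#'
#' @param locations Data frame with `site`, `lon`, `lat`.
#' @param cells Data frame with one row per cell: `cell`, `lon`, `lat`.
#' @return `locations` with an added `cell` column.
#' @export
match_site_cells <- function(locations, cells) {
  cells <- dplyr::arrange(cells, .data$cell)
  pad_lon <- max(diff(sort(unique(cells$lon))), 0.5)
  pad_lat <- max(diff(sort(unique(cells$lat))), 0.5)
  outside <- locations$lon < min(cells$lon) - pad_lon |
    locations$lon > max(cells$lon) + pad_lon |
    locations$lat < min(cells$lat) - pad_lat |
    locations$lat > max(cells$lat) + pad_lat
  if (any(outside)) {
    stop("location(s) outside the grid: ",
         paste(locations$site[outside], collapse = ", "), call. = FALSE)
  }
  idx <- vapply(seq_len(nrow(locations)), function(i) {
    d <- geosphere::distHaversine(
      c(locations$lon[i], locations$lat[i]),
      cbind(cells$lon, cells$lat)
    )
    which.min(d)  # first minimum = lowest cell index after the sort
  }, integer(1))
  locations$cell <- cells$cell[idx]
  tibble::as_tibble(locations)
}

#' Assemble the modelling feature table
#'
#' Joins each location to its grid cell, computes the 30 predictors from the
#' cell's daily series, restricts rows to the taxon analysis window
#' (day-of-year, inclusive) and, when a labelled pollen series is supplied,
#' attaches the binary level outcome. Rows with any missing predictor (or a
#' missing label, when labels are expected) are dropped and counted in a
#' message; no imputation is performed.
#'
#' @param met A met grid table: `cell`, `lon`, `lat`, `alt`, `date`, `tmax`,
#'   `tmin`, `vap`, `wind`, `prec`, `evap`, `rad`.
#' @param locations Sites (`site`, `lon`, `lat`) to extract features for, or
#'   `NULL` to use every grid cell (for map prediction).
#' @param labels Optional labelled pollen table from [assign_levels()],
#'   already filtered to one taxon.
#' @param window Optional `c(min_doy, max_doy)` from [taxon_analysis_window()].
#' @param tbase GDD base temperature (degrees C).
#' @param drop_incomplete Drop rows with missing predictors (default); set
#'   `FALSE` to keep them (used for masked map prediction).
#' @return A tibble with `location`, `date`, the 30 predictors, and `level`
#'   when labels were given.
#' @export
assemble_features <- function(met, locations = NULL, labels = NULL,
                              window = NULL, tbase = 5,
                              drop_incomplete = TRUE) {
  met <- dplyr::arrange(tibble::as_tibble(met), .data$cell, .data$date)
  met$date <- as.Date(met$date)
  cells <- dplyr::distinct(met, .data$cell, .data$lon, .data$lat)

  if (is.null(locations)) {
    loc_map <- tibble::tibble(location = paste0("cell_", cells$cell),
                              cell = cells$cell)
  } else {
    matched <- match_site_cells(locations, cells)
    loc_map <- tibble::tibble(location = as.character(matched$site),
                              cell = matched$cell)
  }

  met_used <- met[met$cell %in% loc_map$cell, ]
  preds <- dplyr::bind_rows(lapply(
    split(met_used, met_used$cell),
    cell_predictors, tbase = tbase
  ))
  feats <- dplyr::inner_join(loc_map, preds, by = "cell",
                             relationship = "many-to-many")
  feats$cell <- NULL

  if (!is.null(window)) {
    if (is.data.frame(window)) window <- c(window$min_doy[1], window$max_doy[1])
    doy <- as.integer(format(feats$date, "%j"))
    feats <- feats[doy >= window[1] & doy <= window[2], ]
  }
  if (!is.null(labels)) {
    if (length(unique(labels$taxon)) > 1) {
      stop("labels must be filtered to a single taxon", call. = FALSE)
    }
    lab <- dplyr::transmute(labels, location = as.character(.data$site),
                            date = as.Date(.data$date), level = .data$level)
    feats <- dplyr::inner_join(feats, lab, by = c("location", "date"))
  }
  if (drop_incomplete) {
    complete <- stats::complete.cases(feats[, predictor_names()])
    if (any(!complete)) {
      message(sum(!complete), " row(s) dropped for missing predictors")
    }
    feats <- feats[complete, ]
  }
  tibble::as_tibble(feats)
}
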