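#' Taxon-specific high-concentration level limits
#'
#' Daily pollen counts at or above these limits (grains/m^3) are labelled
#' "high". The defaults are the first-allergy-symptom limits in use for the
#' three Betulaceae taxa: 35 for Corylus (hazel), 45 for Alnus (alder) and
#' 20 for Betula (birch).
#'
#' @param ... Named taxon = limit pairs overriding or extending the defaults.
#' @return A named numeric vector of limits in grains/m^3.
#' @examples
#' level_thresholds()
#' level_thresholds(Quercus = 80)
#' @export
level_thresholds <- function(...) {
  defaults <- c(Corylus = 35, Alnus = 45, Betula = 20)
  extra <- c(...)
  if (length(extra)) {
    if (is.null(names(extra)) || any(names(extra) == "")) {
      stop("level thresholds must be named by taxon", call. = FALSE)
    }
    defaults[names(extra)] <- extra
  }
  if (any(defaults <= 0)) stop("level limits must be positive", call. = FALSE)
  defaults
}

#' Delimit one pollen season by the 99 % method
#'
#' The season onset is the first day on which the cumulative pollen count
#' reaches 0.5 % of the annual total; the end is the first day on which it
#' reaches 99.5 %. Both crossings are inclusive (cumulative >= the
#' percentage). Days missing from the series contribute zero to the
#' cumulative sum.
#'
#' @param series A data frame with columns `site`, `taxon`, `date`, `count`
#'   covering exactly one site, taxon and calendar year.
#' @param onset_pct,end_pct Cumulative percentage defining onset and end of
#'   the season; the defaults give the 99 % method.
#' @return A one-row tibble: `site`, `taxon`, `year`, `onset_doy`, `end_doy`.
#' @seealso [delimit_seasons()] for a whole multi-site table.
#' @export
delimit_season_99 <- function(series, onset_pct = 0.5, end_pct = 99.5) {
  stopifnot(is.data.frame(series),
            all(c("site", "taxon", "date", "count") %in% names(series)))
  series$date <- as.Date(series$date)
  yr <- unique(as.integer(format(series$date, "%Y")))
  if (length(unique(series$site)) != 1L || length(unique(series$taxon)) != 1L ||
      length(yr) != 1L) {
    stop("delimit_season_99() expects a single site/taxon/year", call. = FALSE)
  }
  if (anyDuplicated(series$date)) stop("duplicate dates in series", call. = FALSE)
  if (any(series$count < 0)) stop("negative pollen counts", call. = FALSE)
  series <- series[order(series$date), ]
  total <- sum(series$count)
  if (total <= 0) {
    stop("no pollen recorded in ", series$site[1], "/", series$taxon[1], "/", yr,
         ": season undefined", call. = FALSE)
  }
  cum <- cumsum(series$count)
  onset_i <- which(cum >= total * onset_pct / 100)[1]
  end_i <- which(cum >= total * end_pct / 100)[1]
  doy <- as.integer(format(series$date, "%j"))
  tibble::tibble(
    site = series$site[1], taxon = series$taxon[1], year = yr,
    onset_doy = doy[onset_i], end_doy = doy[end_i]
  )
}

#' Delimit pollen seasons for every site/taxon/year
#'
#' Applies [delimit_season_99()] to each site-taxon-year group. Site-years
#' with an all-zero annual total have no season under the 99 % method and are
#' dropped with a warning naming them.
#'
#' @param pollen A pollen table (`site`, `taxon`, `date`, `count`).
#' @inheritParams delimit_season_99
#' @return A tibble of season windows, one row per delimited site-year.
#' @export
delimit_seasons <- function(pollen, onset_pct = 0.5, end_pct = 99.5) {
  pollen <- dplyr::mutate(pollen, date = as.Date(.data$date),
                          .year = as.integer(format(as.Date(.data$date), "%Y")))
  groups <- dplyr::group_split(dplyr::group_by(pollen, .data$site, .data$taxon, .data$.year))
  out <- vector("list", length(groups))
  skipped <- character(0)
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (sum(g$count) <= 0) {
      skipped <- c(skipped, paste(g$site[1], g$taxon[1], g$.year[1], sep = "/"))
      next
    }
    out[[i]] <- delimit_season_99(g[c("site", "taxon", "date", "count")],
                                  onset_pct, end_pct)
  }
  if (length(skipped)) {
    warning("no season (all-zero year) for: ", paste(skipped, collapse = ", "),
            call. = FALSE)
  }
  dplyr::bind_rows(out)
}

#' Maximum analysis window per taxon
#'
#' Over all delimited site-year seasons of a taxon, returns the earliest
#' onset and the latest end (day-of-year, inclusive). Downstream modelling
#' restricts every row to this window, mirroring the maximum observed season
#' range (e.g. days 6-150 for Corylus over the Polish monitoring record).
#'
#' @param seasons A season table from [delimit_seasons()].
#' @return A tibble with one row per taxon: `taxon`, `min_doy`, `max_doy`.
#' @export
taxon_analysis_window <- function(seasons) {
  if (!is.data.frame(seasons) || nrow(seasons) == 0) {
    stop("need at least one season window", call. = FALSE)
  }
  dplyr::summarise(dplyr::group_by(seasons, .data$taxon),
                   min_doy = min(.data$onset_doy),
                   max_doy = max(.data$end_doy),
                   .groups = "drop")
}

#' Assign binary concentration levels
#'
#' Labels each daily count `high` when it is at or above the taxon's limit
#' (inclusive: the limit itself is a symptom-triggering concentration) and
#' `low` otherwise.
#'
#' @param pollen A pollen table (`site`, `taxon`, `date`, `count`).
#' @param thresholds Named limits from [level_thresholds()].
#' @return The input with an added `level` factor (`low` < `high`).
#' @export
assign_levels <- function(pollen, thresholds = level_thresholds()) {
  unknown <- setdiff(unique(pollen$taxon), names(thresholds))
  if (length(unknown)) {
    stop("no level limit for taxon: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(pollen),
    level = factor(ifelse(.data$count >= thresholds[as.character(.data$taxon)],
                          "high", "low"),
                   levels = c("low", "high"))
  )
}
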