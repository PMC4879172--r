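#' Per-taxon generative parameters for the synthetic world
#'
#' The latent probability of a high-level day is a Gaussian bump in
#' cumulative growing degree days multiplied by a plateau over the 16-day
#' mean potential evaporation; counts are drawn from a negative binomial
#' whose intensity rises steeply with that probability. Defaults describe a
#' hazel-like (Corylus) taxon: release centred at 32 GDD and favoured by
#' early-season evaporation between 0.6 and 1.7 mm/day.
#'
#' @param gdd_mu Centre of the release window on the cumulative-GDD axis
#'   (degree days).
#' @param gdd_sigma Width of the release window (degree days, > 0).
#' @param evap_lo,evap_hi Favourable band of 16-day mean potential
#'   evaporation (mm/day).
#' @param base_rate Mean count (grains/m^3) at the bump peak; `NULL` anchors
#'   it so that the count median crosses the taxon's level limit exactly at
#'   latent probability 0.5.
#' @param dispersion Negative-binomial overdispersion (the `size` parameter
#'   is `1/dispersion`).
#' @param limit Level limit (grains/m^3); `NULL` takes the taxon default
#'   from [level_thresholds()] when the parameters are used.
#' @return A list of class `taxon_params`.
#' @export
taxon_params <- function(gdd_mu = 32, gdd_sigma = 30, evap_lo = 0.6,
                         evap_hi = 1.7, base_rate = NULL, dispersion = 0.5,
                         limit = NULL) {
  stopifnot(gdd_sigma > 0, evap_lo < evap_hi, dispersion > 0)
  if (!is.null(base_rate) && base_rate <= 0) stop("base_rate must be > 0")
  structure(list(gdd_mu = gdd_mu, gdd_sigma = gdd_sigma, evap_lo = evap_lo,
                 evap_hi = evap_hi, base_rate = base_rate,
                 dispersion = dispersion, limit = limit),
            class = "taxon_params")
}

#' Configuration of the synthetic world
#'
#' Describes a temperate-climate grid of 25 x 25 km cells with daily
#' meteorology, a set of monitoring stations, and one or more pollen taxa
#' whose high-level days follow a known GDD-by-evaporation response with
#' severe class imbalance (the default target is 2.5 % high days, the
#' hazel-like regime).
#'
#' In the absence of noise (`noise_scale = 0`) the daily maximum temperature
#' is exactly the annual sinusoid
#' `t_mean - t_amp * cos(2*pi*(doy - t_phase)/365.25) + t_halfrange`.
#'
#' @param n_cells_x,n_cells_y Grid dimensions (cells; 25 km spacing).
#' @param years Calendar years to simulate (complete years). Include one
#'   leading burn-in year so preceding-year features exist for the first
#'   analysis year.
#' @param n_sites Number of monitoring stations placed on distinct cells.
#' @param taxa Named list of [taxon_params()].
#' @param target_high_fraction Desired fraction of high-level days over all
#'   generated station-days, in (0, 0.5); the generator calibrates the
#'   latent response sharpness to meet it in expectation.
#' @param t_mean,t_amp,t_phase,t_halfrange Annual temperature cycle: mean,
#'   amplitude and coldest day-of-year of the daily mean, and half the
#'   diurnal range (degrees C / day-of-year).
#' @param noise_scale Multiplier on every stochastic met component; 0 gives
#'   a noise-free deterministic climate (and zero precipitation).
#' @param seed RNG seed; the whole world is reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells_x = 10, n_cells_y = 8,
                             years = 2008:2011, n_sites = 11,
                             taxa = list(Corylus = taxon_params()),
                             target_high_fraction = 0.025,
                             t_mean = 8, t_amp = 11, t_phase = 20,
                             t_halfrange = 4, noise_scale = 1, seed = 1) {
  if (n_cells_x < 2 || n_cells_y < 2) {
    stop("grid must be at least 2 x 2 cells", call. = FALSE)
  }
  if (!(target_high_fraction > 0 && target_high_fraction < 0.5)) {
    stop("target_high_fraction must lie in (0, 0.5)", call. = FALSE)
  }
  if (n_sites < 1 || n_sites > n_cells_x * n_cells_y) {
    stop("n_sites must be between 1 and the number of cells", call. = FALSE)
  }
  stopifnot(length(years) >= 1, all(years == as.integer(years)),
            noise_scale >= 0)
  if (is.null(names(taxa)) || any(names(taxa) == "")) {
    stop("taxa must be a named list of taxon_params()", call. = FALSE)
  }
  structure(list(n_cells_x = n_cells_x, n_cells_y = n_cells_y,
                 years = as.integer(years), n_sites = n_sites, taxa = taxa,
                 target_high_fraction = target_high_fraction,
                 t_mean = t_mean, t_amp = t_amp, t_phase = t_phase,
                 t_halfrange = t_halfrange, noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Spatially correlated field: white noise smoothed with a fixed-length
# (3-cell) moving-average kernel, rescaled to the requested sd.
smooth_field <- function(nx, ny, sd, smooth = 3L) {
  z <- matrix(stats::rnorm(nx * ny), ny, nx)
  k <- seq(-smooth, smooth)
  sm_rows <- t(apply(z, 1, function(r) {
    sapply(seq_along(r), function(i) {
      j <- pmin(pmax(i + k, 1), length(r)); mean(r[j])
    })
  }))
  sm <- apply(sm_rows, 2, function(cl) {
    sapply(seq_along(cl), function(i) {
      j <- pmin(pmax(i + k, 1), length(cl)); mean(cl[j])
    })
  })
  s <- stats::sd(as.vector(sm))
  if (s > 0) sm <- sm / s
  sm * sd
}

#' Generate the synthetic meteorological grid
#'
#' Daily fields for every cell and day of the configured years: temperature
#' extremes from the annual sinusoid plus a spatially correlated static
#' offset, a shared AR(1) regional weather anomaly and cell-level noise
#' (with `tmax >= tmin + 0.1` by construction); seasonally modulated vapor
#' pressure, wind speed, global radiation and potential evaporation; and
#' zero-inflated precipitation. Static lon/lat/altitude per cell.
#'
#' @param config A [synthetic_config()].
#' @return A met grid tibble (`cell`, `cell_x`, `cell_y`, `lon`, `lat`,
#'   `alt`, `date`, `tmax`, `tmin`, `vap`, `wind`, `prec`, `evap`, `rad`).
#' @export
generate_met_grid <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nx <- config$n_cells_x; ny <- config$n_cells_y
  ns <- config$noise_scale

  lat0 <- 49; lon0 <- 14
  dlat <- 25 / 110.574
  dlon <- 25 / (111.320 * cos((lat0 + ny * dlat / 2) * pi / 180))
  cells <- tidyr::expand_grid(cell_y = seq_len(ny), cell_x = seq_len(nx))
  cells$cell <- seq_len(nrow(cells))
  cells$lon <- lon0 + (cells$cell_x - 1) * dlon
  cells$lat <- lat0 + (cells$cell_y - 1) * dlat
  alt_f <- smooth_field(nx, ny, 1)
  cells$alt <- round(150 + 90 * as.vector(alt_f)[cells$cell] * ns + 10)

  t_off <- as.vector(smooth_field(nx, ny, 1.2))[cells$cell] * ns
  e_off <- as.vector(smooth_field(nx, ny, 0.15))[cells$cell] * ns

  dates <- seq(as.Date(paste0(min(config$years), "-01-01")),
               as.Date(paste0(max(config$years), "-12-31")), by = "day")
  dates <- dates[as.integer(format(dates, "%Y")) %in% config$years]
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  phase <- cos(2 * pi * (doy - config$t_phase) / 365.25)

  # shared regional AR(1) weather anomaly
  ar <- stats::filter(stats::rnorm(nd, sd = 2.2 * ns), 0.7, method = "recursive")
  ar <- as.numeric(ar)

  grid <- tidyr::expand_grid(cell = cells$cell, date = dates)
  grid <- dplyr::left_join(grid, cells, by = "cell")
  i_d <- match(grid$date, dates)

  tavg_season <- config$t_mean - config$t_amp * phase[i_d]
  tavg <- tavg_season + t_off[grid$cell] + ar[i_d] +
    stats::rnorm(nrow(grid), sd = 1.0 * ns)
  up <- pmax(0.05, config$t_halfrange + stats::rnorm(nrow(grid), sd = 0.8 * ns))
  dn <- pmax(0.05, config$t_halfrange + stats::rnorm(nrow(grid), sd = 0.8 * ns))
  grid$tmax <- tavg + up
  grid$tmin <- tavg - dn

  season01 <- (1 - phase[i_d]) / 2  # 0 midwinter, 1 midsummer
  grid$vap <- pmax(0.5, 6 + 5 * season01 + stats::rnorm(nrow(grid), sd = 0.8 * ns))
  grid$wind <- pmax(0.1, 3.5 + 1.0 * phase[i_d] + stats::rnorm(nrow(grid), sd = 0.9 * ns))
  grid$rad <- pmax(100, 10000 - 8500 * phase[i_d] + stats::rnorm(nrow(grid), sd = 900 * ns))
  grid$evap <- pmax(0.01, 2.2 - 2.0 * phase[i_d] + e_off[grid$cell] +
                      0.15 * ar[i_d] + stats::rnorm(nrow(grid), sd = 0.25 * ns))
  wet <- stats::rbinom(nrow(grid), 1, 0.45)
  amt <- stats::rgamma(nrow(grid), shape = 0.8, scale = 4 + 4 * season01)
  grid$prec <- wet * amt * ns

  dplyr::select(grid, "cell", "cell_x", "cell_y", "lon", "lat", "alt",
                "date", "tmax", "tmin", "vap", "wind", "prec", "evap", "rad")
}

#' Place monitoring stations on the synthetic grid
#'
#' Samples `n_sites` distinct cells and jitters each station inside its
#' cell, mimicking city monitoring sites that do not sit exactly on grid
#' centres.
#'
#' @param met A met grid from [generate_met_grid()].
#' @param config The matching [synthetic_config()].
#' @return A site table (`site`, `lon`, `lat`, `alt`).
#' @export
generate_sites <- function(met, config) {
  set.seed(config$seed + 1L)
  cells <- dplyr::distinct(met, .data$cell, .data$lon, .data$lat, .data$alt)
  picked <- cells[sample(nrow(cells), config$n_sites), ]
  dlon <- min(diff(sort(unique(cells$lon))))
  dlat <- min(diff(sort(unique(cells$lat))))
  tibble::tibble(
    site = sprintf("S%02d", seq_len(config$n_sites)),
    lon = picked$lon + stats::runif(config$n_sites, -0.25, 0.25) * dlon,
    lat = picked$lat + stats::runif(config$n_sites, -0.25, 0.25) * dlat,
    alt = picked$alt
  )
}

# Latent high-level score in [0, 1]: Gaussian bump in lagged cumulative GDD
# times a logistic plateau over the lagged 16-day evaporation mean.
latent_score <- function(gdd_lag, evap16, tp) {
  bump <- exp(-0.5 * ((gdd_lag - tp$gdd_mu) / tp$gdd_sigma)^2)
  w <- 0.08 * (tp$evap_hi - tp$evap_lo)
  band <- stats::plogis((evap16 - tp$evap_lo) / w) *
    stats::plogis((tp$evap_hi - evap16) / w)
  bump * band
}

# Steep logistic ramp of count intensity in the latent probability,
# normalised so g(0)=0, g(1)=1, g(0.5)=0.5.
intensity_ramp <- function(p, a = 16) {
  (stats::plogis(a * (p - 0.5)) - stats::plogis(-a / 2)) /
    (stats::plogis(a / 2) - stats::plogis(-a / 2))
}

# Smallest NB mean whose median reaches the level limit.
anchor_halfway_mean <- function(limit, size) {
  lo <- limit / 4; hi <- 6 * limit
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (stats::qnbinom(0.5, size = size, mu = mid) >= limit) hi <- mid else lo <- mid
  }
  hi
}

#' Generate station pollen counts with known structure
#'
#' For every site, taxon and day, computes the latent high-level probability
#' as a Gaussian bump in 1-day-lagged cumulative GDD times a plateau over
#' the lagged 16-day potential-evaporation mean, sharpened by a calibrated
#' exponent so the expected fraction of high-labelled days matches
#' `target_high_fraction`; then draws negative-binomial counts whose median
#' crosses the taxon's level limit exactly where the latent probability
#' crosses 0.5. The latent truth is stored row-aligned with the counts so
#' recovery tests never re-derive it.
#'
#' @param met A met grid from [generate_met_grid()].
#' @param sites A site table from [generate_sites()] (must lie on the grid).
#' @param config The matching [synthetic_config()].
#' @return A list of class `pollen_world`: `met`, `sites`, `pollen`
#'   (`site`, `taxon`, `date`, `count`), `truth` (row-aligned `p_high`),
#'   `config` and per-taxon `calibration`.
#' @export
generate_pollen_counts <- function(met, sites, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  cells <- dplyr::distinct(met, .data$cell, .data$lon, .data$lat)
  matched <- match_site_cells(sites, cells)

  # per-cell lagged drivers (the same transforms the feature module exposes)
  used <- met[met$cell %in% matched$cell, ]
  drivers <- dplyr::bind_rows(lapply(split(used, used$cell), function(cd) {
    cd <- dplyr::arrange(cd, .data$date)
    e16 <- rolling_mean_lagged(cd$evap, 16)
    first_ok <- which(!is.na(e16))[1]
    e16[seq_len(first_ok - 1)] <- e16[first_ok]
    tibble::tibble(cell = cd$cell, date = cd$date,
                   gdd_lag = accumulate_gdd(cd$date, cd$tmax, cd$tmin),
                   evap16 = e16)
  }))

  limits <- level_thresholds()
  pollen <- list(); truth <- list(); calib <- list()
  for (taxon in names(config$taxa)) {
    tp <- config$taxa[[taxon]]
    limit <- tp$limit %||% unname(limits[taxon])
    if (is.null(limit) || is.na(limit)) {
      stop("no level limit known for synthetic taxon ", taxon, call. = FALSE)
    }
    size <- 1 / tp$dispersion
    bg <- 0.01 * limit
    half <- anchor_halfway_mean(limit, size)
    # anchor so the count mean at latent probability 0.5 equals `half`,
    # putting the NB median at the level limit exactly at p = 0.5
    base_rate <- tp$base_rate %||% (bg + 2 * (half - bg * 0.5^0.3))

    rows <- dplyr::inner_join(matched[c("site", "cell")], drivers,
                              by = "cell", relationship = "many-to-many")
    s <- latent_score(rows$gdd_lag, rows$evap16, tp)
    s <- pmin(pmax(s, 1e-12), 1 - 1e-12)

    # background trace counts follow a wide envelope of the same bump, so
    # counts die off outside the release season as trap data do
    env <- s^0.3
    lambda_of <- function(beta) {
      bg * env + (base_rate - bg) * intensity_ramp(s^beta)
    }
    frac_of <- function(beta) {
      mean(stats::pnbinom(limit - 1, size = size, mu = lambda_of(beta),
                          lower.tail = FALSE))
    }
    lo <- 0.05; hi <- 50
    if (frac_of(lo) < config$target_high_fraction) {
      warning("target high fraction not reachable for ", taxon,
              "; using flattest response", call. = FALSE)
      beta <- lo
    } else {
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        if (frac_of(mid) >= config$target_high_fraction) lo <- mid else hi <- mid
      }
      beta <- lo
    }
    p_high <- s^beta
    counts <- stats::rnbinom(length(p_high), size = size, mu = lambda_of(beta))

    pollen[[taxon]] <- tibble::tibble(site = rows$site, taxon = taxon,
                                      date = rows$date, count = counts)
    truth[[taxon]] <- tibble::tibble(site = rows$site, taxon = taxon,
                                     date = rows$date, p_high = p_high)
    calib[[taxon]] <- list(beta = beta, base_rate = base_rate, bg = bg,
                           limit = limit, expected_high_fraction = frac_of(beta))
  }
  structure(list(met = met, sites = sites,
                 pollen = dplyr::bind_rows(pollen),
                 truth = dplyr::bind_rows(truth),
                 config = config, calibration = calib),
            class = "pollen_world")
}

#' Simulate a complete synthetic world
#'
#' Convenience wrapper: meteorology, station placement and pollen counts in
#' one call, fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A `pollen_world` (see [generate_pollen_counts()]).
#' @examples
#' world <- simulate_pollen_world(synthetic_config(years = 2008:2009, seed = 42))
#' head(world$pollen)
#' @export
simulate_pollen_world <- function(config) {
  met <- generate_met_grid(config)
  sites <- generate_sites(met, config)
  generate_pollen_counts(met, sites, config)
}

#' @export
print.pollen_world <- function(x, ...) {
  cat("<pollen_world>\n")
  cat("  grid:", x$config$n_cells_x, "x", x$config$n_cells_y, "cells;",
      length(unique(x$met$date)), "days\n")
  cat("  sites:", nrow(x$sites), " taxa:",
      paste(names(x$config$taxa), collapse = ", "), "\n")
  for (tx in names(x$calibration)) {
    cal <- x$calibration[[tx]]
    cat(sprintf("  %s: limit %g, expected high fraction %.3f\n",
                tx, cal$limit, cal$expected_high_fraction))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
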