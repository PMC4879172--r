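test_that("daily GDD follows the clamped mean-temperature rule", {
  expect_equal(daily_gdd(15, 5), 5)
  expect_equal(daily_gdd(4, -2), 0)    # max below base: no accumulation
  expect_equal(daily_gdd(6, -10), 0)   # mean below base although max above
  expect_equal(daily_gdd(c(15, 4), c(5, -2)), c(5, 0))
  expect_error(daily_gdd(3, 7), "tmax < tmin")
})

test_that("GDD accumulates from Jan 1, lagged one day, resetting yearly", {
  d <- seq(as.Date("2010-01-01"), by = "day", length.out = 4)
  expect_equal(accumulate_gdd(d, rep(15, 4), rep(5, 4)), c(0, 5, 10, 15))

  # all-winter year: clamp keeps everything at zero
  d365 <- seq(as.Date("2010-01-01"), as.Date("2010-12-31"), by = "day")
  expect_equal(accumulate_gdd(d365, rep(4, 365), rep(-5, 365)), rep(0, 365))

  # year boundary: Dec 31 accumulation does not leak into Jan 1
  d2 <- seq(as.Date("2010-12-30"), as.Date("2011-01-02"), by = "day")
  d2 <- c(seq(as.Date("2010-01-01"), as.Date("2010-12-31"), by = "day"),
          seq(as.Date("2011-01-01"), as.Date("2011-01-02"), by = "day"))
  g <- accumulate_gdd(d2, rep(15, length(d2)), rep(5, length(d2)))
  expect_gt(g[365], 300)
  expect_equal(g[366], 0)
  expect_equal(g[367], 5)

  expect_error(accumulate_gdd(d[c(1, 3)], c(15, 15), c(5, 5)), "gap")
  expect_error(accumulate_gdd(d + 30, rep(15, 4), rep(5, 4)), "January 1")
})

test_that("GDD accumulation is nondecreasing within a year", {
  met <- small_world()$met
  one_cell <- met[met$cell == met$cell[1], ]
  g <- accumulate_gdd(one_cell$date, one_cell$tmax, one_cell$tmin)
  yr <- format(one_cell$date, "%Y")
  for (y in unique(yr)) {
    expect_true(all(diff(g[yr == y]) >= 0))
  }
})

test_that("lagged rolling means match the brute-force window oracle", {
  expect_equal(rolling_mean_lagged(1:5, 4), c(NA, NA, NA, NA, 2.5))
  expect_equal(rolling_mean_lagged(rep(3.2, 10), 4),
               c(rep(NA, 4), rep(3.2, 6)))
  expect_true(is.na(rolling_mean_lagged(1:10, 4)[3]))
  expect_error(rolling_mean_lagged(1:5, 0), "positive")

  set.seed(7)
  for (i in 1:1000) {
    n <- sample(20:60, 1)
    x <- rnorm(n)
    k <- sample(c(4L, 16L, sample(1:19, 1)), 1)
    t <- sample(n, 1)
    expect_equal(rolling_mean_lagged(x, k)[t], oracle_lagged_mean(x, k, t))
  }
})

test_that("preceding-year monthly means are per-month averages of (tmax+tmin)/2", {
  d <- seq(as.Date("2009-01-01"), as.Date("2010-12-31"), by = "day")
  v <- prevyear_monthly_tavg(d, rep(10, length(d)), rep(0, length(d)), 2010)
  expect_equal(unname(v), rep(5, 12))
  expect_named(v, paste0("TAVG_", toupper(month.name), "_PREVYEAR"))

  tmax <- ifelse(format(d, "%Y-%m") == "2009-01", 2, 10)
  tmin <- ifelse(format(d, "%Y-%m") == "2009-01", -4, 0)
  v <- prevyear_monthly_tavg(d, tmax, tmin, 2010)
  expect_equal(unname(v["TAVG_JANUARY_PREVYEAR"]), -1)

  # first year of a record has no preceding year: all features missing
  expect_true(all(is.na(prevyear_monthly_tavg(d, rep(10, length(d)),
                                              rep(0, length(d)), 2009))))
})

test_that("assembled features carry exactly the 30 standard predictors", {
  feats <- small_features()
  expect_true(all(predictor_names() %in% names(feats)))
  expect_length(predictor_names(), 30)
  expect_false(any(is.na(feats[, predictor_names()])))
})

test_that("a site at a cell center inherits that cell's features verbatim", {
  world <- small_world()
  met <- world$met
  cell1 <- dplyr::distinct(met, cell, lon, lat)[1, ]
  site_on <- tibble::tibble(site = "ON", lon = cell1$lon, lat = cell1$lat)
  f <- suppressMessages(assemble_features(met, site_on))
  raw <- met[met$cell == cell1$cell, ]
  day <- f[f$date == as.Date("2009-03-10"), ]
  expect_equal(day$LONGITUDE, cell1$lon)
  expect_equal(day$TMAX_4DAYS_AVG_1DAYLAG,
               mean(raw$tmax[raw$date %in% (as.Date("2009-03-10") - 1:4)]))

  # two sites in one cell: identical predictors, distinct ids
  twins <- tibble::tibble(site = c("T1", "T2"),
                          lon = cell1$lon + c(-0.01, 0.01),
                          lat = cell1$lat + c(0.01, -0.01))
  f2 <- suppressMessages(assemble_features(met, twins))
  wide <- split(f2[, predictor_names()], f2$location)
  expect_equal(wide$T1, wide$T2, ignore_attr = TRUE)
})

test_that("locations outside the grid hull are rejected by name", {
  world <- small_world()
  bad <- tibble::tibble(site = "FAR", lon = 50, lat = 10)
  expect_error(assemble_features(world$met, bad), "FAR")
})

test_that("row count equals sites x window days x years minus dropped rows", {
  world <- small_world()
  lab <- assign_levels(world$pollen)
  win <- c(60, 120)
  msgs <- capture.output(
    feats <- assemble_features(world$met, world$sites, labels = lab,
                               window = win),
    type = "message"
  )
  dropped <- as.integer(sub(" .*", "", msgs[grepl("dropped", msgs)]))
  if (length(dropped) == 0) dropped <- 0
  n_years <- length(unique(format(world$met$date, "%Y")))
  expected <- nrow(world$sites) * (win[2] - win[1] + 1) * n_years - dropped
  expect_equal(nrow(feats), expected)
})
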