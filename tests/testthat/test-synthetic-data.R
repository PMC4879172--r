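tiny_cfg <- function(...) {
  synthetic_config(n_cells_x = 5, n_cells_y = 4, years = 2009:2010,
                   n_sites = 4, seed = 3, ...)
}

test_that("the synthetic world is bit-identical under a fixed seed", {
  w1 <- simulate_pollen_world(tiny_cfg())
  w2 <- simulate_pollen_world(tiny_cfg())
  expect_identical(w1$met, w2$met)
  expect_identical(w1$pollen, w2$pollen)
  expect_identical(w1$truth, w2$truth)
})

test_that("tmax always exceeds tmin by the construction margin", {
  met <- small_world()$met
  expect_true(all(met$tmax >= met$tmin + 0.1))
  expect_true(all(met$prec >= 0))
  expect_true(all(met$rad >= 0))
  expect_true(all(met$evap > 0))
})

test_that("with zero noise the maximum temperature is the stated sinusoid", {
  cfg <- tiny_cfg(noise_scale = 0)
  met <- generate_met_grid(cfg)
  doy <- as.integer(format(met$date, "%j"))
  expected <- cfg$t_mean - cfg$t_amp * cos(2 * pi * (doy - cfg$t_phase) / 365.25) +
    cfg$t_halfrange
  expect_equal(met$tmax, expected, tolerance = 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_cells_x = 1), "at least 2 x 2")
  expect_error(synthetic_config(target_high_fraction = 0.7), "0, 0.5")
  expect_error(synthetic_config(n_sites = 0), "n_sites")
  expect_error(taxon_params(gdd_sigma = -1))
  expect_error(generate_pollen_counts(small_world()$met,
                                      tibble::tibble(site = "BAD", lon = 80,
                                                     lat = 0, alt = 0),
                                      tiny_cfg()),
               "outside the grid")
})

test_that("stored truth peaks at the GDD bump and vanishes in deep winter", {
  world <- small_world()
  tp <- world$config$taxa$Corylus
  met <- world$met
  site_cell <- match_site_cells(world$sites,
                                dplyr::distinct(met, cell, lon, lat))
  drivers <- dplyr::bind_rows(lapply(split(met, met$cell), function(cd) {
    cd <- cd[order(cd$date), ]
    tibble::tibble(cell = cd$cell, date = cd$date,
                   gdd = accumulate_gdd(cd$date, cd$tmax, cd$tmin),
                   evap16 = rolling_mean_lagged(cd$evap, 16))
  }))
  tr <- dplyr::inner_join(
    dplyr::inner_join(world$truth, site_cell[, c("site", "cell")], by = "site"),
    drivers, by = c("cell", "date")
  )
  at_peak <- abs(tr$gdd - tp$gdd_mu) < 2 &
    tr$evap16 > tp$evap_lo + 0.2 & tr$evap16 < tp$evap_hi - 0.2
  expect_true(any(at_peak))
  expect_true(all(tr$p_high[at_peak] > 0.5))

  deep_winter <- tr$gdd == 0 & as.integer(format(tr$date, "%j")) < 20 &
    !is.na(tr$evap16) & tr$evap16 < 0.5 * tp$evap_lo
  expect_true(any(deep_winter))
  expect_true(all(tr$p_high[deep_winter] < 0.05))
})

test_that("realized imbalance tracks the configured target", {
  world <- small_world()
  lab <- assign_levels(world$pollen)
  target <- world$config$target_high_fraction
  realized <- mean(lab$level == "high")
  expect_gt(realized, target * 0.5)
  expect_lt(realized, target * 1.5)

  fractions <- vapply(c(0.02, 0.08, 0.2), function(tgt) {
    w <- simulate_pollen_world(tiny_cfg(target_high_fraction = tgt))
    mean(assign_levels(w$pollen)$level == "high")
  }, numeric(1))
  expect_true(all(diff(fractions) > 0))
})

test_that("labels carry information about the stored truth; shuffling kills it", {
  world <- small_world()
  lab <- assign_levels(world$pollen)
  stopifnot(identical(lab$date, world$truth$date))
  p_bin <- cut(world$truth$p_high, c(-Inf, 0.05, 0.5, Inf))
  high <- lab$level == "high"
  mi <- oracle_mutual_information(p_bin, high)
  expect_gt(mi, 0.01)
  set.seed(1)
  mi_null <- oracle_mutual_information(p_bin, sample(high))
  expect_lt(mi_null, mi / 10)
})

test_that("a generated world round-trips through its CSV files", {
  world <- simulate_pollen_world(tiny_cfg())
  dir <- withr::local_tempdir()
  write_world(world, dir)
  expect_equal(read_pollen_csv(file.path(dir, "pollen.csv")), world$pollen)
  met <- read_met_csv(file.path(dir, "met.csv"))
  expect_equal(met$tmax, world$met$tmax)
  expect_equal(read_sites_csv(file.path(dir, "sites.csv"))$site,
               world$sites$site)
})
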