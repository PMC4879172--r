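# Shared synthetic fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.fixture_cache[[key]])) {
    assign(key, maker(), envir = .fixture_cache)
  }
  .fixture_cache[[key]]
}

# small hazel-like world: 6 x 5 cells, 2 years + burn-in, 6 sites
small_world <- function() {
  cached("small_world", function() {
    simulate_pollen_world(synthetic_config(
      n_cells_x = 6, n_cells_y = 5, years = 2008:2010, n_sites = 6,
      seed = 101
    ))
  })
}

# labelled features of the small world, window-restricted
small_features <- function() {
  cached("small_features", function() {
    world <- small_world()
    lab <- assign_levels(world$pollen)
    win <- taxon_analysis_window(delimit_seasons(lab))
    suppressMessages(
      assemble_features(world$met, world$sites, labels = lab, window = win)
    )
  })
}

# quick classifier on the small world (plumbing-scale tuning)
small_model <- function() {
  cached("small_model", function() {
    spec <- model_spec(ntree = 100, mtry_grid = 5, cv_folds = 3,
                       cv_repeats = 2, seed = 101)
    train_pollen_classifier(small_features(), spec)
  })
}

# cleanly separable two-predictor feature table
separable_features <- function(n = 120, seed = 5) {
  set.seed(seed)
  lev <- rep(c("low", "high"), each = n / 2)
  tibble::tibble(
    f1 = ifelse(lev == "high", 10, 0) + rnorm(n, sd = 0.1),
    f2 = rnorm(n),
    level = factor(lev, levels = c("low", "high"))
  )
}
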