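#' Run the full modelling pipeline on a synthetic world
#'
#' Generates (or reuses) a synthetic world, labels the counts, delimits the
#' taxon analysis window with the 99 % season method, assembles the 30
#' predictors at the monitoring sites, splits the rows into train /
#' temporal-test / spatial-test sets, trains the threshold-optimized
#' classifier and evaluates it on both test sets.
#'
#' @param config A [synthetic_config()] (ignored when `world` is given).
#' @param core_sites,holdout_sites Site ids for [split_spec()]; defaults
#'   use the first `n_sites - 3` sites as core and the last 3 as spatial
#'   hold-outs.
#' @param spec A [model_spec()].
#' @param world Optional pre-generated `pollen_world`.
#' @param taxon Taxon to model; default the world's first.
#' @param thresholds Level limits from [level_thresholds()].
#' @param split_seed Seed of the date-level split; defaults to
#'   `spec$seed`.
#' @return A list of class `pollen_pipeline`: `world`, `window`,
#'   `features`, `splits`, `model`, `eval_temporal`, `eval_spatial`.
#' @export
run_pollen_pipeline <- function(config = synthetic_config(),
                                core_sites = NULL, holdout_sites = NULL,
                                spec = model_spec(),
                                world = NULL, taxon = NULL,
                                thresholds = level_thresholds(),
                                split_seed = NULL) {
  world <- world %||% simulate_pollen_world(config)
  taxon <- taxon %||% names(world$config$taxa)[1]
  pollen <- world$pollen[world$pollen$taxon == taxon, ]
  lab <- assign_levels(pollen, thresholds)
  window <- taxon_analysis_window(delimit_seasons(lab))
  features <- assemble_features(world$met, world$sites, labels = lab,
                                window = window)
  sites <- world$sites$site
  holdout_sites <- holdout_sites %||% utils::tail(sites, 3)
  core_sites <- core_sites %||% setdiff(sites, holdout_sites)
  splits <- make_splits(features,
                        split_spec(core_sites, holdout_sites,
                                   seed = split_seed %||% spec$seed))
  model <- train_pollen_classifier(splits$train, spec)
  structure(list(world = world, window = window, features = features,
                 splits = splits, model = model,
                 eval_temporal = evaluate_model(model, splits$test1),
                 eval_spatial = evaluate_model(model, splits$test2)),
            class = "pollen_pipeline")
}

#' @export
print.pollen_pipeline <- function(x, ...) {
  cat("<pollen_pipeline>\n")
  print(x$model)
  cat("temporal test:\n"); print(x$eval_temporal)
  cat("spatial test:\n"); print(x$eval_spatial)
  invisible(x)
}
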