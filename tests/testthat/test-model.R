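test_that("distance to perfect performance matches direct arithmetic", {
  expect_equal(distance_to_perfect(1, 1, 1, 1), 0)
  expect_equal(distance_to_perfect(0.5, 0.5, 0.5, 0.5), 1.0)
  expect_equal(distance_to_perfect(0.8, 0.9, 0.7, 0.95),
               sqrt(0.2^2 + 0.1^2 + 0.3^2 + 0.05^2))
  expect_error(distance_to_perfect(1.2, 1, 1, 1), "\\[0, 1\\]")
  expect_error(distance_to_perfect(NA, 1, 1, 1))
})

test_that("distance is zero iff perfect and symmetric in its four inputs", {
  set.seed(1)
  for (i in 1:50) {
    m <- runif(4)
    d <- distance_to_perfect(m[1], m[2], m[3], m[4])
    expect_equal(d, distance_to_perfect(m[3], m[1], m[4], m[2]))
    if (any(m < 1)) expect_gt(d, 0)
  }
})

test_that("the threshold grid stays strictly inside (0, 1)", {
  g <- threshold_grid(20)
  expect_length(g, 20)
  expect_equal(g[1], 1 / 21)
  expect_equal(g[20], 20 / 21)
  expect_true(all(g > 0 & g < 1))
})

test_that("threshold optimization returns the smallest zero-distance cutoff when separable", {
  labels <- factor(rep(c("high", "low"), c(10, 40)), levels = c("low", "high"))
  probs <- ifelse(labels == "high", 0.9, 0.1)
  opt <- optimize_threshold(probs, labels, n_thresholds = 20)
  expect_equal(opt$distance, 0)
  # smallest grid cutoff strictly above 0.1 (>= convention)
  expect_equal(opt$threshold_star, 3 / 21)
  expect_s3_class(opt$profile, "tbl_df")
  expect_equal(nrow(opt$profile), 20)
})

test_that("threshold optimization equals the brute-force grid argmin", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(30:120, 1)
    labels <- factor(ifelse(runif(n) < runif(1, 0.1, 0.5), "high", "low"),
                     levels = c("low", "high"))
    if (length(unique(labels)) < 2) next
    probs <- pmin(pmax(runif(n) + 0.3 * (labels == "high"), 0), 1)
    opt <- optimize_threshold(probs, labels, n_thresholds = 20)
    expect_equal(opt$threshold_star,
                 oracle_best_threshold(probs, labels, threshold_grid(20)))
  }
})

test_that("degenerate constant probabilities are flagged non-identifiable", {
  labels <- factor(rep(c("high", "low"), 10), levels = c("low", "high"))
  expect_warning(opt <- optimize_threshold(rep(0.5, 20), labels),
                 "not identifiable")
  expect_false(opt$identifiable)
  expect_equal(nrow(opt$profile), 20)
})

test_that("mtry tuning honours single candidates, tie-breaks and determinism", {
  feats <- separable_features()
  spec <- model_spec(ntree = 60, mtry_grid = 2, cv_folds = 3, cv_repeats = 2,
                     seed = 9)
  tuned <- tune_mtry(feats, spec)
  expect_equal(tuned$mtry_star, 2)

  spec2 <- model_spec(ntree = 60, mtry_grid = c(1, 2), cv_folds = 3,
                      cv_repeats = 2, seed = 9)
  tuned2 <- tune_mtry(feats, spec2)
  # separable data: every candidate reaches ~zero distance, smallest mtry wins
  expect_true(all(tuned2$cv_results$distance < 0.05))
  expect_equal(tuned2$mtry_star, 1)

  rerun <- tune_mtry(feats, spec2)
  expect_identical(tuned2$mtry_star, rerun$mtry_star)
  expect_identical(tuned2$oof$prob, rerun$oof$prob)
})

test_that("single-class data cannot be tuned or fitted", {
  feats <- separable_features()
  feats$level <- factor("low", levels = c("low", "high"))
  expect_error(tune_mtry(feats, model_spec()), "single class")
  expect_error(fit_forest(feats, 2), "single class")
})

test_that("the forest separates separable data and is seed-stable", {
  feats <- separable_features(n = 200)
  spec <- model_spec(ntree = 100, seed = 4)
  fit <- fit_forest(feats, mtry = 1, spec = spec)
  probs <- predict(fit, feats, type = "prob")
  expect_gte(oracle_auc(probs, feats$level == "high"), 0.99)
  fit2 <- fit_forest(feats, mtry = 1, spec = spec)
  expect_identical(probs, predict(fit2, feats, type = "prob"))
})

test_that("label permutation reduces the forest to a prevalence guesser", {
  world <- small_world()
  feats <- small_features()
  set.seed(12)
  null_feats <- dplyr::mutate(feats, level = sample(level))
  spec <- model_spec(ntree = 100, mtry_grid = 5, cv_folds = 3, cv_repeats = 1,
                     seed = 12)
  tuned <- tune_mtry(null_feats, spec)
  opt <- optimize_threshold(tuned$oof$prob, tuned$oof$label, 20)
  # a no-skill model cannot approach the perfect corner; the prevalence
  # guesser's distance with these marginals exceeds 1
  expect_gt(opt$distance, 0.9)
})

test_that("held-out permutation importance isolates signal from noise", {
  set.seed(31)
  n <- 400
  signal <- rnorm(n)
  feats <- tibble::tibble(
    signal = signal,
    noise1 = rnorm(n),
    noise2 = rnorm(n),
    level = factor(ifelse(signal + rnorm(n, sd = 0.3) > 0.8, "high", "low"),
                   levels = c("low", "high"))
  )
  spec <- model_spec(ntree = 100, seed = 31)
  fit <- fit_forest(feats, mtry = 2, spec = spec)
  imp <- permutation_importance(fit, feats, seed = 31)
  expect_equal(imp$term[1], "signal")
  expect_lt(max(abs(imp$importance[imp$term != "signal"])), 0.05)

  # a constant column cannot change under permutation: drop exactly 0
  feats$flat <- 1
  fit2 <- fit_forest(feats, mtry = 2, spec = spec,
                     predictors = c("signal", "noise1", "noise2", "flat"))
  imp2 <- permutation_importance(fit2, feats, seed = 31)
  expect_equal(imp2$importance[imp2$term == "flat"], 0)
})

test_that("probability profiles are bounded and flag constant predictors", {
  feats <- separable_features(n = 150)
  fit <- fit_forest(feats, mtry = 1, spec = model_spec(ntree = 80, seed = 2))
  prof <- probability_profile(fit, feats, "f1", bins = 20)
  expect_true(all(prof$mean_prob >= 0 & prof$mean_prob <= 1))
  # noise predictor: flat profile around the overall mean, on fresh rows
  fresh <- separable_features(n = 600, seed = 77)
  prof_noise <- probability_profile(fit, fresh, "f2", bins = 10)
  overall <- mean(predict(fit, fresh, type = "prob"))
  filled <- prof_noise$n >= 20  # tail bins hold too few rows to average
  expect_gte(sum(filled), 5)
  expect_true(all(abs(prof_noise$mean_prob[filled] - overall) < 0.1))

  feats$const <- 2
  fit2 <- fit_forest(feats, mtry = 1, spec = model_spec(ntree = 50, seed = 2),
                     predictors = c("f1", "const"))
  expect_warning(p1 <- probability_profile(fit2, feats, "const"),
                 "constant")
  expect_equal(nrow(p1), 1)
})
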