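#' Model specification
#'
#' Tuning parameters for the imbalance-aware random-forest classifier:
#' 500 trees, mtry chosen by repeated stratified k-fold cross-validation,
#' and a grid of candidate probability cutoffs evaluated on pooled
#' out-of-fold predictions. The reference protocol is 100 repetitions of
#' ten-fold CV with 20 thresholds; `cv_repeats`/`cv_folds` scale down for
#' desk-scale runs without changing the procedure.
#'
#' @param ntree Number of trees per forest.
#' @param mtry_grid Candidate numbers of predictors per split; `NULL` picks
#'   a small default grid from the number of predictors at fit time.
#' @param cv_folds,cv_repeats Folds and repetitions of the stratified CV.
#' @param n_thresholds Number of evenly spaced candidate cutoffs.
#' @param seed Seed driving every random step of training.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(ntree = 500, mtry_grid = NULL, cv_folds = 10,
                       cv_repeats = 100, n_thresholds = 20, seed = 1) {
  stopifnot(ntree >= 1, cv_folds >= 2, cv_repeats >= 1, n_thresholds >= 2)
  if (!is.null(mtry_grid)) {
    stopifnot(all(mtry_grid >= 1), !anyDuplicated(mtry_grid))
  }
  structure(list(ntree = as.integer(ntree), mtry_grid = mtry_grid,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 n_thresholds = as.integer(n_thresholds),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Evenly spaced probability-cutoff grid
#'
#' `n` cutoffs at `i/(n+1)` for `i = 1..n`, so the grid stays strictly
#' inside (0, 1); n = 20 gives 0.0476..0.9524.
#'
#' @param n Number of cutoffs.
#' @return Numeric vector of length `n`.
#' @export
threshold_grid <- function(n = 20) {
  stopifnot(n >= 2)
  seq_len(n) / (n + 1)
}

#' Distance to perfect classification
#'
#' Euclidean distance between (sensitivity, specificity, PPV, NPV) and the
#' perfect point (1, 1, 1, 1):
#' `sqrt((1-Sens)^2 + (1-Spec)^2 + (1-Ppv)^2 + (1-Npv)^2)`.
#' Minimizing it over candidate cutoffs balances all four metrics under
#' class imbalance. Ranges from 0 (perfect) to 2.
#'
#' @param sens,spec,ppv,npv Metric values in \[0, 1\] (undefined values must
#'   be resolved by the caller before this arithmetic; the threshold
#'   optimizer maps them to 0 to penalize degenerate cutoffs).
#' @return The distance, vectorized over its inputs.
#' @examples
#' distance_to_perfect(1, 1, 1, 1)          # 0
#' distance_to_perfect(0.5, 0.5, 0.5, 0.5)  # 1
#' @export
distance_to_perfect <- function(sens, spec, ppv, npv) {
  vals <- cbind(sens, spec, ppv, npv)
  if (anyNA(vals) || any(vals < 0 | vals > 1)) {
    stop("all four metrics must lie in [0, 1]", call. = FALSE)
  }
  sqrt((1 - sens)^2 + (1 - spec)^2 + (1 - ppv)^2 + (1 - npv)^2)
}

# labels as logical is-high
.as_high <- function(labels) {
  if (is.logical(labels)) return(labels)
  lv <- as.character(labels)
  if (!all(lv %in% c("low", "high"))) {
    stop('labels must be "low"/"high" (or logical)', call. = FALSE)
  }
  lv == "high"
}

# Sens/Spec/Ppv/Npv of probs >= thr; undefined ratios are NA here.
metrics_at_threshold <- function(probs, labels, thr) {
  truth <- .as_high(labels)
  pred <- probs >= thr
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  rat <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  list(sens = rat(tp, fn), spec = rat(tn, fp),
       ppv = rat(tp, fp), npv = rat(tn, fn))
}

#' Optimize the probability cutoff on resampled predictions
#'
#' Evaluates every cutoff of [threshold_grid()] on out-of-fold class
#' probabilities: for each cutoff computes sensitivity, specificity, PPV
#' and NPV (prediction is `high` when probability >= cutoff) and the
#' [distance_to_perfect()], with undefined PPV/NPV entering the distance as
#' 0 so degenerate cutoffs are penalized. Returns the cutoff minimizing the
#' distance (the smallest cutoff on ties) and the full per-cutoff profile.
#'
#' @param probs Out-of-fold probabilities of the high class, in \[0, 1\].
#' @param labels Matching `low`/`high` labels (both classes present).
#' @param n_thresholds Number of candidate cutoffs.
#' @return A list of class `threshold_opt`: `threshold_star`, `distance`,
#'   `profile` (tibble: threshold, sens, spec, ppv, npv, distance) and
#'   `identifiable`.
#' @export
optimize_threshold <- function(probs, labels, n_thresholds = 20) {
  stopifnot(length(probs) == length(labels),
            all(probs >= 0 & probs <= 1))
  truth <- .as_high(labels)
  if (length(unique(truth)) < 2) {
    stop("both classes must be present to optimize a threshold", call. = FALSE)
  }
  grid <- threshold_grid(n_thresholds)
  prof <- purrr::map_dfr(grid, function(thr) {
    m <- metrics_at_threshold(probs, labels, thr)
    zero <- function(x) ifelse(is.na(x), 0, x)
    tibble::tibble(threshold = thr, sens = m$sens, spec = m$spec,
                   ppv = m$ppv, npv = m$npv,
                   distance = distance_to_perfect(zero(m$sens), zero(m$spec),
                                                  zero(m$ppv), zero(m$npv)))
  })
  identifiable <- length(unique(probs)) > 1
  if (!identifiable) {
    warning("all probabilities identical: threshold not identifiable",
            call. = FALSE)
  }
  best <- which.min(prof$distance)  # first minimum = smallest cutoff
  structure(list(threshold_star = prof$threshold[best],
                 distance = prof$distance[best],
                 profile = prof, identifiable = identifiable),
            class = "threshold_opt")
}

# feature columns used for modelling
model_predictors <- function(features, predictors = NULL) {
  if (!is.null(predictors)) return(predictors)
  std <- intersect(predictor_names(), names(features))
  if (length(std)) return(std)
  setdiff(names(features)[vapply(features, is.numeric, logical(1))],
          c("location", "date", "level"))
}

.check_two_classes <- function(labels) {
  if (length(unique(.as_high(labels))) < 2) {
    stop("training data contain a single class", call. = FALSE)
  }
}

#' Tune mtry by repeated stratified cross-validation
#'
#' For each candidate mtry, runs `cv_repeats` repetitions of stratified
#' `cv_folds`-fold CV, pooling out-of-fold high-class probabilities; each
#' candidate is scored by the minimum [distance_to_perfect()] over the
#' cutoff grid on its pooled predictions, and the candidate with the
#' smallest score wins (smallest mtry on ties). The winner's pooled
#' out-of-fold probabilities are returned for threshold optimization.
#'
#' @param features A feature table with a `level` outcome column.
#' @param spec A [model_spec()].
#' @param predictors Predictor columns; defaults to the standard 30 (or all
#'   numeric columns for non-standard tables).
#' @return A list: `mtry_star`, `oof` (tibble: prob, label), `cv_results`
#'   (tibble: mtry, distance, threshold).
#' @export
tune_mtry <- function(features, spec = model_spec(), predictors = NULL) {
  predictors <- model_predictors(features, predictors)
  .check_two_classes(features$level)
  p <- length(predictors)
  grid <- spec$mtry_grid %||% unique(pmax(1, pmin(p, c(2, floor(sqrt(p)), floor(p / 3), floor(p / 2)))))
  grid <- sort(unique(pmin(grid, p)))

  set.seed(spec$seed)
  truth <- .as_high(features$level)
  n <- nrow(features)
  # fold assignments shared across candidates so the comparison is paired
  folds <- replicate(spec$cv_repeats, {
    f <- integer(n)
    for (cl in unique(truth)) {
      idx <- which(truth == cl)
      f[idx] <- sample(rep_len(seq_len(spec$cv_folds), length(idx)))
    }
    f
  })
  fit_seeds <- matrix(sample.int(.Machine$integer.max,
                                 spec$cv_repeats * spec$cv_folds * length(grid)),
                      ncol = length(grid))

  x <- as.data.frame(features[, predictors])
  y <- factor(ifelse(truth, "high", "low"), levels = c("low", "high"))

  oof_by_m <- vector("list", length(grid))
  score <- thr <- numeric(length(grid))
  for (mi in seq_along(grid)) {
    probs <- numeric(0); labs <- logical(0)
    s <- 0L
    for (r in seq_len(spec$cv_repeats)) {
      f <- folds[, r]
      for (k in seq_len(spec$cv_folds)) {
        s <- s + 1L
        hold <- f == k
        if (length(unique(y[!hold])) < 2) next
        fit <- ranger::ranger(x = x[!hold, , drop = FALSE], y = y[!hold],
                              num.trees = spec$ntree, mtry = grid[mi],
                              probability = TRUE, num.threads = 1,
                              seed = fit_seeds[s, mi])
        pr <- stats::predict(fit, x[hold, , drop = FALSE],
                             num.threads = 1)$predictions[, "high"]
        probs <- c(probs, pr); labs <- c(labs, truth[hold])
      }
    }
    opt <- optimize_threshold(probs, labs, spec$n_thresholds)
    score[mi] <- opt$distance
    thr[mi] <- opt$threshold_star
    oof_by_m[[mi]] <- tibble::tibble(prob = probs, label = labs)
  }
  best <- which.min(score)  # first = smallest mtry on ties
  list(mtry_star = grid[best],
       oof = dplyr::mutate(oof_by_m[[best]],
                           label = factor(ifelse(.data$label, "high", "low"),
                                          levels = c("low", "high"))),
       cv_results = tibble::tibble(mtry = grid, distance = score,
                                   threshold = thr))
}

#' Fit the probability forest
#'
#' Fits `ntree` classification trees with `mtry` candidate predictors per
#' split, exposing class probabilities for new rows.
#'
#' @inheritParams tune_mtry
#' @param mtry Number of candidate predictors per split.
#' @return An object of class `pollen_forest`.
#' @export
fit_forest <- function(features, mtry, spec = model_spec(), predictors = NULL) {
  predictors <- model_predictors(features, predictors)
  .check_two_classes(features$level)
  y <- factor(as.character(features$level), levels = c("low", "high"))
  fit <- ranger::ranger(x = as.data.frame(features[, predictors]), y = y,
                        num.trees = spec$ntree, mtry = min(mtry, length(predictors)),
                        probability = TRUE, num.threads = 1, seed = spec$seed)
  structure(list(forest = fit, predictors = predictors, mtry = mtry,
                 spec = spec, n_train = nrow(features)),
            class = "pollen_forest")
}

#' @export
predict.pollen_forest <- function(object, newdata, type = c("prob", "level"),
                                  threshold = NULL, ...) {
  type <- match.arg(type)
  missing_p <- setdiff(object$predictors, names(newdata))
  if (length(missing_p)) {
    stop("newdata lacks predictors: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  prob <- stats::predict(object$forest,
                         as.data.frame(newdata[, object$predictors]),
                         num.threads = 1)$predictions[, "high"]
  if (type == "prob") return(unname(prob))
  thr <- threshold %||% object$threshold_star
  if (is.null(thr) || is.na(thr)) {
    stop("no probability threshold available; supply `threshold`",
         call. = FALSE)
  }
  factor(ifelse(prob >= thr, "high", "low"), levels = c("low", "high"))
}

#' Train the full high-pollen-level classifier
#'
#' The complete training path: mtry tuning by repeated stratified CV,
#' probability-cutoff optimization on the winner's pooled out-of-fold
#' predictions, a final forest fit on all rows, and permutation variable
#' importance. Deterministic given `spec$seed`.
#'
#' @inheritParams tune_mtry
#' @return An object of class `pollen_classifier` (also a `pollen_forest`):
#'   the fitted forest plus `mtry_star`, `threshold_star`, `importance`,
#'   `resample_profile` (per-cutoff metrics, the threshold-tuning curves)
#'   and `cv_results`.
#' @export
train_pollen_classifier <- function(features, spec = model_spec(),
                                    predictors = NULL) {
  predictors <- model_predictors(features, predictors)
  tuned <- tune_mtry(features, spec, predictors)
  opt <- optimize_threshold(tuned$oof$prob, tuned$oof$label, spec$n_thresholds)
  fitted <- fit_forest(features, tuned$mtry_star, spec, predictors)
  fitted$threshold_star <- opt$threshold_star
  fitted$oof_distance <- opt$distance
  fitted$resample_profile <- opt$profile
  fitted$cv_results <- tuned$cv_results
  class(fitted) <- c("pollen_classifier", class(fitted))
  fitted$importance <- permutation_importance(fitted, features,
                                              seed = spec$seed)
  fitted
}

#' @export
print.pollen_classifier <- function(x, ...) {
  cat("<pollen_classifier>\n")
  cat(sprintf("  %d trees, mtry = %d, threshold = %.3f (oof distance %.3f)\n",
              x$spec$ntree, x$mtry, x$threshold_star, x$oof_distance))
  cat(sprintf("  %d predictors, %d training rows\n",
              length(x$predictors), x$n_train))
  top <- utils::head(x$importance, 3)
  cat("  top predictors:", paste(top$term, collapse = ", "), "\n")
  invisible(x)
}

#' Permutation variable importance (mean decrease in accuracy)
#'
#' Held-out permutation importance: the rows are split into stratified
#' folds, a forest with the model's tuning is refitted on the remainder of
#' each fold, and for every predictor the drop in held-out classification
#' accuracy (class assigned at the model's optimized cutoff, or 0.5 when
#' none is set) after permuting that column is recorded over several
#' permutation rounds. Drops are averaged over folds and rounds and
#' reported in descending order. Held-out evaluation matters: on the
#' training rows themselves a forest is saturated and single-column
#' permutations barely move its hard-threshold accuracy.
#'
#' @param model A `pollen_forest` / `pollen_classifier`.
#' @param features A labelled feature table.
#' @param n_folds Stratified held-out folds to refit over.
#' @param n_perm Permutation rounds per predictor and fold.
#' @param threshold Cutoff for class assignment; default is the model's.
#' @param seed Seed for fold assignment and permutations.
#' @return A tibble (`term`, `importance`, `rank`), sorted descending.
#' @export
permutation_importance <- function(model, features, n_folds = 3, n_perm = 3,
                                   threshold = NULL, seed = 1) {
  thr <- threshold %||% model$threshold_star %||% 0.5
  if (is.na(thr)) thr <- 0.5
  truth <- .as_high(features$level)
  y <- factor(ifelse(truth, "high", "low"), levels = c("low", "high"))
  x <- as.data.frame(features[, model$predictors])

  set.seed(seed)
  fold <- integer(nrow(features))
  for (cl in unique(truth)) {
    idx <- which(truth == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  drops <- matrix(0, length(model$predictors), n_folds,
                  dimnames = list(model$predictors, NULL))
  for (k in seq_len(n_folds)) {
    hold <- fold == k
    fit <- ranger::ranger(x = x[!hold, , drop = FALSE], y = y[!hold],
                          num.trees = model$spec$ntree, mtry = model$mtry,
                          probability = TRUE, num.threads = 1,
                          seed = seed + k)
    acc <- function(df) {
      pr <- stats::predict(fit, df, num.threads = 1)$predictions[, "high"]
      mean((pr >= thr) == truth[hold])
    }
    xh <- x[hold, , drop = FALSE]
    base <- acc(xh)
    for (v in model$predictors) {
      d <- vapply(seq_len(n_perm), function(r) {
        perm <- xh
        perm[[v]] <- sample(perm[[v]])
        base - acc(perm)
      }, numeric(1))
      drops[v, k] <- mean(d)
    }
  }
  out <- tibble::tibble(term = model$predictors,
                        importance = unname(rowMeans(drops)))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  out$rank <- seq_len(nrow(out))
  out
}

#' Observed probability profile of a predictor
#'
#' Bins a predictor over its observed range and averages the model's
#' predicted high-class probability per bin, tracing how the predicted risk
#' responds to the variable (e.g. the GDD release window).
#'
#' @param model A `pollen_forest` / `pollen_classifier`.
#' @param features A feature table to profile over.
#' @param predictor Name of the predictor.
#' @param bins Number of equal-width bins.
#' @return A tibble (`bin_center`, `mean_prob`, `n`).
#' @export
probability_profile <- function(model, features, predictor, bins = 50) {
  if (!predictor %in% names(features)) {
    stop("unknown predictor: ", predictor, call. = FALSE)
  }
  x <- features[[predictor]]
  prob <- predict(model, features, type = "prob")
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("constant predictor: single-bin profile", call. = FALSE)
    return(tibble::tibble(bin_center = rng[1], mean_prob = mean(prob),
                          n = length(x)))
  }
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  bin <- cut(x, br, include.lowest = TRUE, labels = FALSE)
  centers <- (br[-1] + br[-length(br)]) / 2
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, prob = prob), .data$bin),
    mean_prob = mean(.data$prob), n = dplyr::n(), .groups = "drop"
  )
  tibble::tibble(bin_center = centers[out$bin], mean_prob = out$mean_prob,
                 n = out$n)
}
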