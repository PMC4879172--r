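#' Specification of the train / temporal-test / spatial-test split
#'
#' Core sites contribute a date-level random split: a fraction of their
#' distinct dates (default 2/3) forms the training set and the remaining
#' dates the first (temporal) test set, so no date appears on both sides.
#' Hold-out sites contribute every row to the second (spatial) test set,
#' measuring transferability to unmonitored locations.
#'
#' @param core_sites Sites whose dates are split into train/test1.
#' @param holdout_sites Sites entirely reserved for test2 (disjoint from
#'   `core_sites`).
#' @param train_fraction Fraction of core dates used for training.
#' @param seed Seed of the random date partition.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(core_sites, holdout_sites, train_fraction = 2 / 3,
                       seed = 1) {
  if (length(intersect(core_sites, holdout_sites))) {
    stop("core and holdout sites must be disjoint", call. = FALSE)
  }
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(core_sites = core_sites, holdout_sites = holdout_sites,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a feature table into train, temporal test and spatial test sets
#'
#' @param features A feature table with `location` and `date` columns.
#' @param spec A [split_spec()].
#' @return A list of tibbles: `train`, `test1` (held-out dates of the core
#'   sites), `test2` (all rows of the hold-out sites).
#' @export
make_splits <- function(features, spec) {
  stopifnot(inherits(spec, "split_spec"))
  core <- features[features$location %in% spec$core_sites, ]
  test2 <- features[features$location %in% spec$holdout_sites, ]
  dates <- sort(unique(core$date))
  set.seed(spec$seed)
  n_train <- floor(length(dates) * spec$train_fraction)
  train_dates <- sample(dates, n_train)
  list(train = core[core$date %in% train_dates, ],
       test1 = core[!core$date %in% train_dates, ],
       test2 = test2)
}

#' Confusion matrix with high = positive
#'
#' @param labels,predictions Equal-length `low`/`high` vectors (factors,
#'   characters, or logical is-high).
#' @return A one-row tibble of class `confusion_matrix`: `TP` (high
#'   predicted high), `FP` (low predicted high), `TN`, `FN`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  truth <- .as_high(labels)
  pred <- .as_high(predictions)
  out <- tibble::tibble(TP = sum(pred & truth), FP = sum(pred & !truth),
                        TN = sum(!pred & !truth), FN = sum(!pred & truth))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Build a confusion matrix directly from counts
#'
#' Useful for recomputing published metrics from printed counts.
#'
#' @param TP,FP,TN,FN Nonnegative cell counts.
#' @return A `confusion_matrix` tibble.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0, TP + FP + TN + FN > 0)
  out <- tibble::tibble(TP = TP, FP = FP, TN = TN, FN = FN)
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Kappa, sensitivity, specificity, PPV and NPV of a confusion matrix
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN); Kappa = (O - E)/(1 - E) with observed accuracy
#' O = (TP+TN)/n and expected accuracy E from the marginal totals,
#' E = ((TP+FN)(TP+FP) + (TN+FP)(TN+FN))/n^2. Ratios with a zero
#' denominator (and Kappa when E = 1) are reported as `NA` — flagged as
#' undefined rather than silently zeroed, since this is a reporting
#' context.
#'
#' @param cm A `confusion_matrix`.
#' @return A one-row tibble: `kappa`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, plus the four counts and `n`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$TP; fp <- cm$FP; tn <- cm$TN; fn <- cm$FN
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  rat <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  o <- (tp + tn) / n
  e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (e == 1) NA_real_ else (o - e) / (1 - e)
  tibble::tibble(kappa = kappa,
                 sensitivity = rat(tp, fn), specificity = rat(tn, fp),
                 ppv = rat(tp, fp), npv = rat(tn, fn),
                 TP = tp, FP = fp, TN = tn, FN = fn, n = n)
}

#' Evaluate a trained classifier on a labelled test set
#'
#' Predicts high-class probabilities, applies the optimized cutoff
#' (probability >= cutoff is high) and returns the confusion matrix with
#' its metric report. Run separately on the temporal (`test1`) and spatial
#' (`test2`) sets.
#'
#' @param model A `pollen_classifier`.
#' @param test A labelled feature table.
#' @param threshold Optional cutoff override.
#' @return A list of class `model_evaluation`: `confusion`, `metrics`,
#'   `threshold`, `n`.
#' @export
evaluate_model <- function(model, test, threshold = NULL) {
  if (!"level" %in% names(test) || anyNA(test$level)) {
    stop("test rows must be labelled", call. = FALSE)
  }
  thr <- threshold %||% model$threshold_star
  prob <- predict(model, test, type = "prob")
  pred <- prob >= thr
  cm <- confusion(test$level, pred)
  structure(list(confusion = cm, metrics = compute_metrics(cm),
                 threshold = thr, n = nrow(test)),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<model_evaluation> n = %d, threshold = %.3f\n", x$n, x$threshold))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", m$TP, m$FP, m$TN, m$FN))
  cat(sprintf("  kappa %.2f  sens %.2f  spec %.2f  ppv %.2f  npv %.2f\n",
              m$kappa, m$sensitivity, m$specificity, m$ppv, m$npv))
  invisible(x)
}
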