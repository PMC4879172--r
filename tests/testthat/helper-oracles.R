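# Independent brute-force oracles the implementation is checked against.

# season bounds by a plain cumulative scan
oracle_season <- function(counts, onset_pct = 0.5, end_pct = 99.5) {
  total <- sum(counts)
  cum <- 0
  onset <- end <- NA_integer_
  for (i in seq_along(counts)) {
    cum <- cum + counts[i]
    if (is.na(onset) && cum >= total * onset_pct / 100) onset <- i
    if (is.na(end) && cum >= total * end_pct / 100) { end <- i; break }
  }
  c(onset = onset, end = end)
}

# window mean of the k days strictly before t
oracle_lagged_mean <- function(x, k, t) {
  if (t - k < 1) return(NA_real_)
  mean(x[(t - k):(t - 1)])
}

# grid argmin of the distance to perfect, smallest threshold on ties
oracle_best_threshold <- function(probs, labels, grid) {
  dist <- vapply(grid, function(thr) {
    pred <- probs >= thr
    truth <- labels == "high"
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
    r <- function(a, b) if (a + b == 0) 0 else a / (a + b)
    sqrt((1 - r(tp, fn))^2 + (1 - r(tn, fp))^2 +
           (1 - r(tp, fp))^2 + (1 - r(tn, fn))^2)
  }, numeric(1))
  grid[which.min(dist)]
}

# rank-based AUC (probability a random high outranks a random low)
oracle_auc <- function(probs, is_high) {
  r <- rank(probs)
  n1 <- sum(is_high); n0 <- sum(!is_high)
  (sum(r[is_high]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Cohen's kappa from the four counts
oracle_kappa <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  o <- (tp + tn) / n
  e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  (o - e) / (1 - e)
}

# simple plug-in mutual information between two discrete vectors (nats)
oracle_mutual_information <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  }
  mi
}

random_pollen_series <- function(n_days = 120, year = 2010) {
  counts <- rpois(n_days, lambda = rexp(n_days, 1 / 5))
  if (sum(counts) == 0) counts[sample(n_days, 1)] <- 1L
  tibble::tibble(site = "X", taxon = "Corylus",
                 date = seq(as.Date(paste0(year, "-01-01")), by = "day",
                            length.out = n_days),
                 count = counts)
}
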