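# k-fold cross-validated single-feature linear discriminant classification
# per percentile criterion, with exclusion of degenerate (single-class)
# folds.

#' Random k-fold assignment
#'
#' Random partition of `n` observations into `k` folds whose sizes differ by
#' at most 1 (non-stratified). Seeded and reproducible.
#'
#' @param n number of observations.
#' @param k number of folds (`2 <= k <= n`).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(n, k, seed = 1L) {
  if (k > n) stop_param("k (", k, ") must not exceed n (", n, ")")
  if (k < 2) stop_param("k must be >= 2")
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

# one-feature Fisher linear discriminant with pooled within-class variance:
# score(x) = (x - (m1 + m0)/2) * (m1 - m0) / s2_pooled. Monotone in x with
# the sign of the training mean difference, hence AUC-equivalent to the raw
# feature oriented by that sign.
lda_score <- function(train_x, train_good, new_x) {
  m1 <- mean(train_x[train_good]); m0 <- mean(train_x[!train_good])
  n1 <- sum(train_good); n0 <- sum(!train_good)
  ss <- sum((train_x[train_good] - m1)^2) + sum((train_x[!train_good] - m0)^2)
  s2 <- if (n1 + n0 > 2) ss / (n1 + n0 - 2) else 0
  w <- if (s2 > 0) (m1 - m0) / s2 else (m1 - m0)
  (new_x - (m1 + m0) / 2) * w
}

#' Validation-fold AUC of a one-feature linear discriminant
#'
#' Fits a pooled-variance linear discriminant on the training records and
#' scores the validation records by the discriminant score; returns the
#' validation AUC of that score. A fold whose training or validation labels
#' contain a single class is excluded (sensitivity/specificity and the
#' discriminant are undefined), returning `NA` with the reason.
#'
#' @param train_x,train_labels training feature values and logical labels
#'   (`TRUE` = good performer).
#' @param val_x,val_labels validation feature values and labels.
#' @return list with `auc` (`NA` when excluded), `excluded` (logical),
#'   `reason` (`NA`, `"single-class-training"` or `"single-class-validation"`).
#' @export
lda_fold_auc <- function(train_x, train_labels, val_x, val_labels) {
  if (length(train_x) == 0 || length(val_x) == 0)
    stop_input("empty training or validation partition")
  train_labels <- as.logical(train_labels); val_labels <- as.logical(val_labels)
  if (!any(train_labels) || all(train_labels))
    return(list(auc = NA_real_, excluded = TRUE, reason = "single-class-training"))
  if (!any(val_labels) || all(val_labels))
    return(list(auc = NA_real_, excluded = TRUE, reason = "single-class-validation"))
  sc <- lda_score(train_x, train_labels, val_x)
  list(auc = empirical_auc(sc, val_labels), excluded = FALSE,
       reason = NA_character_)
}

#' Cross-validated percentile AUC sweep
#'
#' For each percentile criterion on the (optionally age-adjusted) composite:
#' labels good/poor performers, splits the sample into `k` random folds
#' (single seeded assignment shared across percentiles), computes the
#' validation AUC of a one-feature linear discriminant per fold, excludes
#' degenerate folds, and averages AUC over the retained folds. Percentiles
#' with zero retained folds are reported missing.
#'
#' @param scored scored cohort.
#' @param predictor predictor column name.
#' @param orientation `"higher_better"` or `"lower_better"` (see
#'   [run_sweep()]).
#' @param k number of folds; the conventional set is 2, 5 or 10, enforced
#'   unless `allow_any_k`.
#' @param seed integer seed for the fold assignment.
#' @param adjust_age label on age-residualized composite.
#' @param percentiles percentile grid.
#' @param allow_any_k permit fold counts outside `{2, 5, 10}`.
#' @return object of class `cv_result`: `table` (percentile, n_good, n_poor,
#'   retained_folds, excluded_folds, mean_auc) and `summary` (mean/sd of
#'   mean_auc over the grid), plus the configuration.
#' @export
cv_sweep <- function(scored, predictor, orientation = "higher_better",
                     k = 2, seed = 1L, adjust_age = FALSE,
                     percentiles = 1:99, allow_any_k = FALSE) {
  if (!allow_any_k && !k %in% c(2, 5, 10))
    stop_param("k must be one of 2, 5, 10 (use allow_any_k to override)")
  if (!predictor %in% names(scored)) stop_input("missing predictor column: ", predictor)
  keep <- !is.na(scored$composite) & !is.na(scored[[predictor]]) &
    (!adjust_age | !is.na(scored$age))
  comp <- scored$composite[keep]
  x <- orient_scores(scored[[predictor]][keep], orientation)
  n <- length(comp)
  if (n < 10) stop_input("need at least 10 complete rows")
  if (k > n / 2) stop_param("k must be <= n/2")
  target <- if (adjust_age) age_adjust_cognition(comp, scored$age[keep]) else comp
  folds <- make_folds(n, k, seed)
  rows <- lapply(percentiles, function(p) {
    lab <- label_by_percentile(target, p)
    res <- lapply(seq_len(k), function(f) {
      tr <- folds != f
      lda_fold_auc(x[tr], lab[tr], x[!tr], lab[!tr])
    })
    exc <- vapply(res, `[[`, logical(1), "excluded")
    aucs <- vapply(res, `[[`, numeric(1), "auc")
    data.frame(percentile = p, n_good = sum(lab), n_poor = sum(!lab),
               retained_folds = sum(!exc), excluded_folds = sum(exc),
               mean_auc = if (any(!exc)) mean(aucs[!exc]) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$mean_auc)
  structure(list(
    table = tab,
    summary = list(mean_auc = mean(tab$mean_auc[ok]),
                   sd_auc = sd(tab$mean_auc[ok]),
                   n = n, k = k, missing_percentiles = sum(!ok)),
    predictor = predictor, orientation = orientation,
    adjust_age = adjust_age, k = k, seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_result> %s, k = %d%s: mean AUC %.3f (sd %.3f), %d missing percentile(s), n = %d\n",
              x$predictor, x$k, if (x$adjust_age) ", age-adjusted" else "",
              s$mean_auc, s$sd_auc, s$missing_percentiles, s$n))
  invisible(x)
}
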