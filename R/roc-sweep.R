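# Percentile-criterion ROC/AUC sweep: good/poor labeling at each percentile
# of the cognitive composite, rank-based empirical AUC, Youden-optimal
# cutoffs, optional age adjustment of the labeling variable, and the
# random-predictor chance band.

#' Label good/poor performers at a percentile criterion
#'
#' The cutoff is the empirical quantile at `p` percent (linear-interpolation
#' quantile, R type 7). Participants at or above the cutoff are good
#' performers, below it poor performers.
#'
#' @param values numeric vector (composite z or residualized composite).
#' @param p percentile strictly inside (0, 100).
#' @return logical vector, `TRUE` = good performer.
#' @export
#' @examples
#' label_by_percentile(c(1, 2, 3, 4), 50)  # FALSE FALSE TRUE TRUE
label_by_percentile <- function(values, p) {
  if (p <= 0 || p >= 100) stop_param("percentile must be strictly inside (0, 100)")
  if (length(values) < 2) stop_input("need at least 2 values")
  if (max(values) - min(values) == 0)
    stop_input("degenerate input: all values identical")
  cutoff <- quantile(values, p / 100, type = 7, names = FALSE)
  values >= cutoff
}

#' Empirical AUC (Mann-Whitney probability)
#'
#' The area under the empirically constructed ROC curve equals the
#' probability that a randomly chosen positive (good performer) has a higher
#' score than a randomly chosen negative, ties counted 1/2. Computed from
#' midranks in O(n log n).
#'
#' @param scores numeric biomarker values, oriented so higher = predicted
#'   good.
#' @param labels logical, `TRUE` = good performer (positive class).
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop_input("degenerate input: both classes must be non-empty")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-optimal cutoff
#'
#' Scans all midpoints between adjacent sorted unique scores (plus -Inf and
#' +Inf) with the decision rule "score >= cutoff predicts good", and returns
#' the cutoff maximizing Youden's J = sensitivity + specificity - 1. Ties are
#' broken toward higher specificity, then toward the lower cutoff.
#'
#' @param scores oriented biomarker values (higher = predicted good).
#' @param labels logical, `TRUE` = good.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop_input("degenerate input: both classes must be non-empty")
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  pos <- scores[labels]; neg <- scores[!labels]
  sens <- vapply(cand, function(c) mean(pos >= c), numeric(1))
  spec <- vapply(cand, function(c) mean(neg < c), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[spec[best] == max(spec[best])]
  if (length(best) > 1) best <- best[which.min(cand[best])]
  list(cutoff = cand[best], sensitivity = sens[best], specificity = spec[best],
       j = j[best])
}

#' Age-adjust the cognitive composite
#'
#' Residualizes the composite on age by OLS (intercept included); percentile
#' labeling downstream then operates on what age does not explain.
#'
#' @param composite numeric composite values.
#' @param age years.
#' @return numeric residuals (same length; `NA` rows propagate).
#' @export
age_adjust_cognition <- function(composite, age) {
  ok <- !is.na(composite) & !is.na(age)
  if (sum(ok) < 3) stop_input("need at least 3 complete observations")
  if (sd(age[ok]) == 0) stop_input("degenerate input: age is constant")
  out <- rep(NA_real_, length(composite))
  out[ok] <- resid(lm(composite[ok] ~ age[ok]))
  out
}

# orientation: "higher_better" (e.g. wave V amplitude: larger predicts good)
# or "lower_better" (e.g. wave V latency: larger predicts poor)
orient_scores <- function(x, orientation) {
  orientation <- match.arg(orientation, c("higher_better", "lower_better"))
  if (orientation == "lower_better") -x else x
}

#' Percentile-criterion ROC/AUC sweep
#'
#' For each percentile criterion on the (optionally age-adjusted) cognitive
#' composite, labels good/poor performers, computes the empirical AUC of the
#' oriented predictor and the Youden-optimal cutoff. Cutoffs are reported in
#' the predictor's original units with their decision direction (for a
#' lower-is-better predictor such as latency: values above the cutoff predict
#' poor performance). Percentiles where labeling yields a single class are
#' recorded as missing points, not failures.
#'
#' @param scored scored cohort with `composite`, `age` and the predictor.
#' @param predictor predictor column name.
#' @param orientation `"higher_better"` or `"lower_better"`: fixed a priori
#'   per feature (amplitude up = good; latency up = poor), never chosen to
#'   maximize AUC.
#' @param adjust_age label on age-residualized composite instead of the raw
#'   one.
#' @param percentiles integer grid, default 1..99.
#' @return object of class `sweep_curve`: `table` (percentile, n_good,
#'   n_poor, auc, cutoff, cutoff_direction, sensitivity, specificity) and
#'   `summary` (mean/sd/min/max AUC over the grid, argmax percentile), plus
#'   the configuration.
#' @export
run_sweep <- function(scored, predictor, orientation = "higher_better",
                      adjust_age = FALSE, percentiles = 1:99) {
  if (!predictor %in% names(scored)) stop_input("missing predictor column: ", predictor)
  if (any(percentiles <= 0 | percentiles >= 100))
    stop_param("percentiles must be strictly inside (0, 100)")
  keep <- !is.na(scored$composite) & !is.na(scored[[predictor]]) &
    (!adjust_age | !is.na(scored$age))
  comp <- scored$composite[keep]
  x <- scored[[predictor]][keep]
  n <- length(comp)
  if (n < 10) stop_input("need at least 10 complete rows")
  target <- if (adjust_age) age_adjust_cognition(comp, scored$age[keep]) else comp
  s <- orient_scores(x, orientation)
  lower <- orientation == "lower_better"
  rows <- lapply(percentiles, function(p) {
    lab <- label_by_percentile(target, p)
    ng <- sum(lab); np <- n - ng
    if (ng == 0 || np == 0) {
      return(data.frame(percentile = p, n_good = ng, n_poor = np,
                        auc = NA_real_, cutoff = NA_real_,
                        cutoff_direction = NA_character_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        stringsAsFactors = FALSE))
    }
    auc <- empirical_auc(s, lab)
    yc <- youden_cutoff(s, lab)
    data.frame(percentile = p, n_good = ng, n_poor = np, auc = auc,
               cutoff = if (lower) -yc$cutoff else yc$cutoff,
               cutoff_direction = if (lower) "above_predicts_poor" else "above_predicts_good",
               sensitivity = yc$sensitivity, specificity = yc$specificity,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$auc)
  summary <- list(
    mean_auc = mean(tab$auc[ok]), sd_auc = sd(tab$auc[ok]),
    min_auc = if (any(ok)) min(tab$auc[ok]) else NA_real_,
    max_auc = if (any(ok)) max(tab$auc[ok]) else NA_real_,
    argmax_percentile = if (any(ok)) tab$percentile[ok][which.max(tab$auc[ok])] else NA_integer_,
    n = n)
  structure(list(table = tab, summary = summary, predictor = predictor,
                 orientation = orientation, adjust_age = adjust_age),
            class = "sweep_curve")
}

#' @export
print.sweep_curve <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sweep_curve> %s (%s%s): mean AUC %.3f (sd %.3f, range %.3f-%.3f), peak at percentile %d, n = %d\n",
              x$predictor, x$orientation,
              if (x$adjust_age) ", age-adjusted" else "",
              s$mean_auc, s$sd_auc, s$min_auc, s$max_auc,
              s$argmax_percentile, s$n))
  invisible(x)
}

# AUC-only sweep on pre-oriented scores; reuses one rank pass per replicate
# via precomputed good/poor masks. Used by chance_band, where Youden cutoffs
# are not needed.
sweep_auc_mean <- function(masks, scores) {
  r <- rank(scores, ties.method = "average")
  aucs <- vapply(masks, function(m) {
    ng <- sum(m); np <- length(m) - ng
    (sum(r[m]) - ng * (ng + 1) / 2) / (ng * np)
  }, numeric(1))
  aucs
}

percentile_masks <- function(target, percentiles) {
  masks <- lapply(percentiles, function(p) {
    lab <- label_by_percentile(target, p)
    if (all(lab) || !any(lab)) NULL else lab
  })
  masks[!vapply(masks, is.null, logical(1))]
}

#' Chance band from randomly generated predictors
#'
#' Replaces the ABR predictor with independent standard-normal draws and
#' reruns the percentile AUC sweep for each replicate. Because the AUC is
#' invariant to monotone transforms of the scores, any continuous null
#' distribution gives the same band; standard normal draws are used. Reports
#' the per-replicate grid-mean AUCs and, because the dispersion can be read
#' either across replicates or across percentiles, both SDs.
#'
#' @param scored scored cohort (only `composite`, and `age` if adjusting,
#'   are used).
#' @param replicates number of random predictors.
#' @param seed integer seed.
#' @param adjust_age label on age-residualized composite.
#' @param percentiles percentile grid.
#' @return list of class `chance_band`: `replicate_mean_auc` (vector),
#'   `mean`, `sd_across_replicates`, `sd_across_percentiles`,
#'   `percentile_mean_auc`.
#' @export
chance_band <- function(scored, replicates = 1000, seed = 1L,
                        adjust_age = FALSE, percentiles = 1:99) {
  if (replicates < 1) stop_param("replicates must be >= 1")
  keep <- !is.na(scored$composite) & (!adjust_age | !is.na(scored$age))
  comp <- scored$composite[keep]
  n <- length(comp)
  target <- if (adjust_age) age_adjust_cognition(comp, scored$age[keep]) else comp
  masks <- percentile_masks(target, percentiles)
  with_seed(seed, {
    per_rep <- matrix(NA_real_, replicates, length(masks))
    for (b in seq_len(replicates)) {
      per_rep[b, ] <- sweep_auc_mean(masks, rnorm(n))
    }
    rep_means <- rowMeans(per_rep)
    perc_means <- colMeans(per_rep)
    structure(list(replicate_mean_auc = rep_means,
                   mean = mean(rep_means),
                   sd_across_replicates = sd(rep_means),
                   sd_across_percentiles = sd(perc_means),
                   percentile_mean_auc = perc_means,
                   n = n, replicates = replicates, seed = seed),
              class = "chance_band")
  })
}

#' @export
print.chance_band <- function(x, ...) {
  cat(sprintf("<chance_band> mean AUC %.4f (sd across %d replicates %.4f; across percentiles %.4f), n = %d\n",
              x$mean, x$replicates, x$sd_across_replicates,
              x$sd_across_percentiles, x$n))
  invisible(x)
}

#' Paired comparison of two sweep curves
#'
#' Two-sided paired t test of AUC across the common percentile grid points of
#' two sweeps (e.g. age-adjusted vs unadjusted). Grid points are statistically
#' dependent, so the p-value is descriptive rather than strictly valid; it
#' mirrors the conventional summary comparison of such curves.
#'
#' @param a,b `sweep_curve` objects (or `cv_result`; anything with a `table`
#'   containing `percentile` and a mean-AUC column).
#' @return list with `mean_a`, `mean_b`, `mean_diff`, `p`, `n_points`.
#' @export
compare_sweeps <- function(a, b) {
  col <- function(x) if ("auc" %in% names(x$table)) "auc" else "mean_auc"
  ta <- x_tab(a); tb <- x_tab(b)
  common <- intersect(ta$percentile[!is.na(ta[[col(a)]])],
                      tb$percentile[!is.na(tb[[col(b)]])])
  if (length(common) < 3) stop_input("fewer than 3 common percentiles")
  va <- ta[[col(a)]][match(common, ta$percentile)]
  vb <- tb[[col(b)]][match(common, tb$percentile)]
  tt <- t.test(va, vb, paired = TRUE)
  list(mean_a = mean(va), mean_b = mean(vb), mean_diff = mean(va - vb),
       p = tt$p.value, n_points = length(common))
}

x_tab <- function(x) {
  if (is.data.frame(x)) x else x$table
}
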