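test_that("percentile labeling follows the linear-interpolation quantile", {
  expect_identical(label_by_percentile(c(1, 2, 3, 4), 50),
                   c(FALSE, FALSE, TRUE, TRUE))
  # 1st percentile on 118 distinct values: one or two poor performers
  x <- seq_len(118)
  lab <- label_by_percentile(x, 1)
  expect_true(sum(!lab) %in% c(1, 2))
  # location invariance
  set.seed(1)
  v <- rnorm(50)
  for (p in c(10, 30, 70)) {
    expect_identical(label_by_percentile(v, p), label_by_percentile(v + 10, p))
  }
  expect_error(label_by_percentile(rep(1, 5), 30), "identical")
  expect_error(label_by_percentile(v, 0), "percentile")
  expect_error(label_by_percentile(v, 100), "percentile")
})

test_that("empirical AUC equals the all-pairs Mann-Whitney probability", {
  expect_equal(empirical_auc(c(2, 3, 1), c(TRUE, TRUE, FALSE)), 1.0)
  expect_equal(empirical_auc(c(2, 3, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 0.875)
  set.seed(5)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    scores <- sample(rnorm(n), n, replace = TRUE)  # ties likely
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_identical(empirical_auc(scores, labels), brute_auc(scores, labels))
  }
  expect_error(empirical_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC matches an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    scores <- rnorm(n)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(labels) || all(labels)) next
    ref <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                          predictor = scores,
                                          direction = "<", quiet = TRUE)))
    expect_equal(empirical_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("AUC is monotone-invariant and label-symmetric", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    scores <- rnorm(n)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    a <- empirical_auc(scores, labels)
    expect_equal(empirical_auc(exp(2 * scores), labels), a, tolerance = 1e-12)
    expect_equal(empirical_auc(-scores, labels), 1 - a, tolerance = 1e-12)
    expect_equal(empirical_auc(-scores, !labels), a, tolerance = 1e-12)
  }
})

test_that("random labels give chance-level AUC on average", {
  set.seed(8)
  scores <- rnorm(60)
  aucs <- replicate(500, {
    lab <- sample(c(rep(TRUE, 30), rep(FALSE, 30)))
    empirical_auc(scores, lab)
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.01)
})

test_that("Youden cutoff maximizes J and respects the stated tie-breaks", {
  y <- youden_cutoff(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(y$cutoff, 2.5)
  expect_equal(y$j, 1)
  expect_equal(y$sensitivity, 1); expect_equal(y$specificity, 1)
  # exhaustive oracle: J evaluated at every candidate cutoff
  set.seed(4)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    scores <- round(rnorm(n), 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    y <- youden_cutoff(scores, labels)
    cand <- c(-Inf, sort(unique(scores)), Inf)
    j_all <- vapply(cand, function(c) {
      mean(scores[labels] >= c) + mean(scores[!labels] < c) - 1
    }, numeric(1))
    expect_equal(y$j, max(j_all), tolerance = 1e-12)
  }
  # translation equivariance
  sc <- c(0.1, 0.5, 0.2, 0.9, 0.8); lb <- c(FALSE, TRUE, FALSE, TRUE, TRUE)
  a <- youden_cutoff(sc, lb); b <- youden_cutoff(sc + 3, lb)
  expect_equal(b$cutoff, a$cutoff + 3, tolerance = 1e-12)
  expect_equal(b$j, a$j, tolerance = 1e-12)
})

test_that("age adjustment residualizes the composite on age", {
  set.seed(2)
  age <- runif(50, 18, 92)
  comp <- -0.021 * age
  expect_equal(age_adjust_cognition(comp, age), rep(0, 50), tolerance = 1e-10)
  comp2 <- rnorm(50)
  adj <- age_adjust_cognition(comp2, age)
  expect_equal(adj, resid(lm(comp2 ~ age)), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(age_adjust_cognition(comp2, rep(50, 50)), "constant")
})

test_that("a perfect biomarker sweeps at AUC 1 everywhere", {
  sc <- make_scored(seed = 10)
  sc$self <- sc$composite
  sw <- run_sweep(sc, "self", orientation = "higher_better")
  expect_true(all(sw$table$auc[!is.na(sw$table$auc)] == 1))
  expect_equal(sw$summary$mean_auc, 1)
})

test_that("an independent predictor sweeps near chance", {
  # a single replicate has SD ~0.05 around 0.5; average a few
  sc <- make_scored(seed = 12)
  set.seed(77)
  means <- replicate(30, {
    sc$noise <- rnorm(nrow(sc))
    run_sweep(sc, "noise")$summary$mean_auc
  })
  expect_lt(abs(mean(means) - 0.5), 0.03)
})

test_that("sweep output is well-formed and cutoffs keep original units and direction", {
  sc <- make_scored(seed = 14)
  sw_lat <- run_sweep(sc, "wave_v_latency", orientation = "lower_better")
  tab <- sw_lat$table
  expect_identical(tab$percentile, 1:99)
  expect_true(all(tab$n_good + tab$n_poor == sw_lat$summary$n))
  ok <- !is.na(tab$auc)
  expect_true(all(tab$auc[ok] >= 0 & tab$auc[ok] <= 1))
  expect_true(all(tab$cutoff_direction[ok] == "above_predicts_poor"))
  # cutoffs live on the latency scale
  expect_true(all(tab$cutoff[ok] > 4 & tab$cutoff[ok] < 8))
  # reported sensitivity/specificity reproduce from the cutoff at one grid point
  row <- tab[tab$percentile == 30, ]
  lab <- label_by_percentile(sc$composite, 30)
  sens <- mean(sc$wave_v_latency[lab] <= row$cutoff + 1e-12)
  expect_equal(row$sensitivity, sens, tolerance = 1e-9)

  sw_amp <- run_sweep(sc, "wave_v_amplitude", orientation = "higher_better")
  ok2 <- !is.na(sw_amp$table$auc)
  expect_true(all(sw_amp$table$cutoff_direction[ok2] == "above_predicts_good"))
  # with calibrated effects both wave V features beat chance on average
  expect_gt(sw_lat$summary$mean_auc, 0.55)
  expect_gt(sw_amp$summary$mean_auc, 0.55)
})

test_that("age adjustment attenuates AUC for age-correlated predictors on average", {
  diffs <- vapply(1:10, function(s) {
    sc <- make_scored(seed = 500 + s)
    raw <- run_sweep(sc, "wave_v_amplitude", orientation = "higher_better")
    adj <- run_sweep(sc, "wave_v_amplitude", orientation = "higher_better",
                     adjust_age = TRUE)
    raw$summary$mean_auc - adj$summary$mean_auc
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("the chance band is centered at 0.5 and reproducible", {
  sc <- make_scored(seed = 20)
  cb <- chance_band(sc, replicates = 200, seed = 99)
  expect_equal(cb$mean, 0.5, tolerance = 0.01)
  cb2 <- chance_band(sc, replicates = 200, seed = 99)
  expect_identical(cb$replicate_mean_auc, cb2$replicate_mean_auc)
  expect_length(cb$replicate_mean_auc, 200)
  # permutation null agrees with fresh-draw null to Monte-Carlo error
  set.seed(42)
  perm_means <- replicate(100, {
    sc$permuted <- sample(sc$wave_v_amplitude)
    run_sweep(sc, "permuted")$summary$mean_auc
  })
  expect_equal(mean(perm_means), cb$mean, tolerance = 0.02)
})

test_that("sweep comparison runs a paired test over common percentiles", {
  sc <- make_scored(seed = 25)
  raw <- run_sweep(sc, "wave_v_latency", orientation = "lower_better")
  adj <- run_sweep(sc, "wave_v_latency", orientation = "lower_better",
                   adjust_age = TRUE)
  cmp <- compare_sweeps(raw, adj)
  expect_true(cmp$n_points <= 99 && cmp$n_points >= 90)
  expect_equal(cmp$mean_diff, cmp$mean_a - cmp$mean_b, tolerance = 1e-12)
  expect_true(cmp$p >= 0 && cmp$p <= 1)
})
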