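test_that("a perfect linear relation gives B = 1 with a collapsed CI", {
  d <- data.frame(x = 1:20, y = 1:20)
  f <- suppressWarnings(fit_linear_model(d, "y", "x"))  # lm warns on exact fit
  expect_equal(f$B, 1, tolerance = 1e-12)
  expect_lt(diff(f$ci95), 1e-10)
})

test_that("age-adjusted B equals the residual-on-residual slope (Frisch-Waugh)", {
  for (s in 1:20) {
    set.seed(s)
    n <- 60
    d <- data.frame(age = runif(n, 18, 92))
    d$x <- 0.01 * d$age + rnorm(n)
    d$y <- -0.02 * d$age + 0.3 * d$x + rnorm(n)
    f <- fit_linear_model(d, "y", "x", adjust_for = "age")
    ry <- resid(lm(y ~ age, d)); rx <- resid(lm(x ~ age, d))
    expect_equal(f$B, unname(coef(lm(ry ~ rx))[2]), tolerance = 1e-10)
  }
})

test_that("for z-scored x and y the univariate B equals the Pearson correlation", {
  for (s in 1:10) {
    set.seed(100 + s)
    d <- data.frame(x = rnorm(40))
    d$y <- 0.5 * d$x + rnorm(40)
    d$y <- as.numeric(scale(d$y))
    f <- fit_linear_model(d, "y", "x", z_predictor = TRUE)
    expect_equal(f$B, cor(d$x, d$y) * sd(d$y), tolerance = 1e-10)
    d$x <- as.numeric(scale(d$x))
    f2 <- fit_linear_model(d, "y", "x")
    expect_equal(f2$B, cor(d$x, d$y), tolerance = 1e-10)
  }
})

test_that("the null rejection rate stays near the nominal level", {
  set.seed(7)
  p_vals <- replicate(400, {
    d <- data.frame(x = rnorm(100), y = rnorm(100))
    fit_linear_model(d, "y", "x")$p
  })
  expect_lt(mean(p_vals < 0.05), 0.09)
  expect_gt(mean(p_vals < 0.05), 0.015)
})

test_that("preconditions are enforced", {
  d <- data.frame(x = rnorm(25), z = rnorm(25))
  d$y <- d$x + rnorm(25)
  expect_error(fit_linear_model(d, "y", "y"), "differ")
  expect_error(fit_linear_model(d, "y", "x", adjust_for = "y"), "outcome")
  expect_error(fit_linear_model(d[1:12, ], "y", "x", adjust_for = "z"),
               "insufficient")
  d$x2 <- d$x
  expect_error(fit_linear_model(d, "y", "x", adjust_for = "x2"),
               "rank-deficient")
})

test_that("diagnostics pass on model-true data and warn on violations", {
  set.seed(11)
  d <- data.frame(x = rnorm(200))
  d$y <- 1 + 0.5 * d$x + rnorm(200)
  ok <- model_diagnostics(fit_linear_model(d, "y", "x"))
  expect_true(all(ok$status == "pass"))
  # a quadratic truth violates linearity (and typically homoscedasticity)
  d2 <- data.frame(x = seq(-3, 3, length.out = 200))
  d2$y <- d2$x^2 + rnorm(200, 0, 0.1)
  bad <- model_diagnostics(fit_linear_model(d2, "y", "x"))
  expect_true(bad$status[bad$check == "linearity"] == "warn" ||
                bad$status[bad$check == "heteroscedasticity"] == "warn")
  # near-duplicate predictors inflate VIF
  set.seed(12)
  d3 <- data.frame(x = rnorm(100))
  d3$x2 <- d3$x + rnorm(100, 0, 1e-4)
  d3$y <- d3$x + rnorm(100)
  vif_row <- model_diagnostics(fit_linear_model(d3, "y", "x", adjust_for = "x2"))
  expect_identical(vif_row$status[vif_row$check == "multicollinearity"], "warn")
})

test_that("zero-residual cohorts reproduce the generating wave V slopes exactly", {
  p <- cohort_params(seed = 6)
  p$cognition_model$sd <- 0
  p$domain_noise_sd <- 0
  g <- generate_cohort(p)
  sc <- score_cohort(g$cohort)
  # sample z-scoring rescales the noiseless composite; test on the latent one
  sc$latent <- g$truth$latent_composite
  der <- g$truth$derived
  # per-unit slopes: both wave V features plus age span the exact model
  f_lat <- fit_linear_model(sc, "latent", "wave_v_latency",
                            adjust_for = c("age", "wave_v_amplitude"))
  expect_equal(f_lat$B, p$cognition_model$latency_slope / der$sd_wave_v_latency,
               tolerance = 1e-8)
  f_amp <- fit_linear_model(sc, "latent", "wave_v_amplitude",
                            adjust_for = c("age", "wave_v_latency"))
  expect_equal(f_amp$B, p$cognition_model$amplitude_slope / der$sd_wave_v_amplitude,
               tolerance = 1e-8)
})

test_that("the association suite covers the model grid and survives failures", {
  sc <- make_scored(seed = 8)
  suite <- run_association_suite(sc, diagnostics = FALSE)
  expect_true(all(c("subgroup", "outcome", "predictor", "adjusted", "B",
                    "ci_low", "ci_high", "p", "note") %in% names(suite)))
  # full sample x (composite + 10 domains) x 9 predictors x (1 or 2 adjustments)
  all_rows <- suite[suite$subgroup == "all", ]
  expect_equal(nrow(all_rows), 11 * (1 + 8 * 2))
  ok <- all_rows[!is.na(all_rows$B), ]
  expect_true(all(ok$ci_low <= ok$B & ok$B <= ok$ci_high))
  expect_true(all(ok$p >= 0 & ok$p <= 1))
  # subgroup rows exist and failed rows carry notes instead of aborting
  expect_true(any(suite$subgroup == "young"))
  sub <- make_scored(seed = 8)
  sub$hearing_category[sub$age_group == "young"] <- "normal"
  suite2 <- run_association_suite(sub[sub$age_group == "young", ,
                                      drop = FALSE], diagnostics = FALSE)
  expect_true(any(!is.na(suite2$note)))  # constant hearing predictor fails
})

test_that("permuted outcomes give a near-nominal false-positive rate across the suite", {
  sc <- make_scored(seed = 13)
  set.seed(21)
  rates <- replicate(10, {
    perm <- sc
    idx <- sample(nrow(perm))
    cols <- c("composite", paste0("z_", default_domains()$measure))
    perm[cols] <- perm[idx, cols]
    suite <- run_association_suite(perm, subgroups = FALSE,
                                   hearing_binary = FALSE,
                                   diagnostics = FALSE)
    mean(suite$p < 0.05, na.rm = TRUE)
  })
  expect_lt(mean(rates), 0.12)
})

test_that("age-group comparisons report F and Bonferroni post-hocs", {
  sc <- make_scored(seed = 3)
  cmp <- compare_age_groups(sc, "composite")
  expect_length(cmp$F, 1)
  expect_equal(nrow(cmp$pairwise), 3)
  expect_true(all(cmp$pairwise$p_bonferroni >= 0 & cmp$pairwise$p_bonferroni <= 1))

  # identical duplicated groups: zero difference, adjusted p = 1
  set.seed(30)
  d <- data.frame(y = rep(rnorm(20), 2),
                  age_group = rep(c("a", "b"), each = 20))
  cmp2 <- compare_age_groups(d, "y")
  expect_equal(cmp2$pairwise$mean_diff, 0, tolerance = 1e-12)
  expect_equal(cmp2$pairwise$p_bonferroni, 1, tolerance = 1e-12)

  # well-separated groups: all post-hocs significant
  set.seed(31)
  d3 <- data.frame(y = c(rnorm(50), rnorm(50, 1), rnorm(50, 2)),
                   age_group = rep(c("a", "b", "c"), each = 50))
  cmp3 <- compare_age_groups(d3, "y")
  expect_true(all(cmp3$pairwise$p_bonferroni < 0.01))
  expect_error(compare_age_groups(d3[d3$age_group == "a", ], "y"), "2 groups")
})

test_that("group F test is null-calibrated on identically distributed groups", {
  set.seed(17)
  p_vals <- replicate(200, {
    d <- data.frame(y = rnorm(60), age_group = rep(c("a", "b", "c"), 20))
    compare_age_groups(d, "y")$p
  })
  expect_lt(mean(p_vals < 0.05), 0.11)
  expect_gt(mean(p_vals < 0.05), 0.01)
})
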