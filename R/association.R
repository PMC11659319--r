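# Linear association suite: univariate and covariate-adjusted OLS with
# t-based CIs, model diagnostics, the full outcome x predictor grid, and
# age-group comparisons with Bonferroni-corrected post-hocs.

#' Fit one linear association model
#'
#' Ordinary least squares of `outcome` on `predictor` plus optional
#' covariates (typically age in raw years). Reports the predictor's slope B,
#' its t-based 95% CI and two-sided p, following the convention of at least
#' 10 observations per independent variable.
#'
#' @param data data.frame.
#' @param outcome,predictor column names.
#' @param adjust_for character vector of covariate column names.
#' @param z_predictor standardize the predictor to sample z-units first
#'   (covariates and outcome are left in their own units).
#' @param subset optional logical vector selecting rows before fitting.
#' @param min_per_iv minimum observations per independent variable.
#' @return list of class `assoc_fit`: `B`, `ci95`, `p`, `n`, `outcome`,
#'   `predictor`, `adjust_for`, `fit` (the `lm` object).
#' @export
fit_linear_model <- function(data, outcome, predictor,
                             adjust_for = character(0), z_predictor = FALSE,
                             subset = NULL, min_per_iv = 10L) {
  if (outcome == predictor) stop_input("outcome and predictor must differ")
  if (outcome %in% adjust_for) stop_input("covariates must not include the outcome")
  vars <- c(outcome, predictor, adjust_for)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop_input("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  d <- data[, vars, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  n_iv <- 1L + length(adjust_for)
  if (nrow(d) < min_per_iv * n_iv)
    stop_input(sprintf("insufficient n (%d) for %d independent variable(s)",
                       nrow(d), n_iv))
  if (z_predictor) {
    s <- sd(d[[predictor]])
    if (is.na(s) || s == 0) stop_input("predictor has zero variance: ", predictor)
    d[[predictor]] <- (d[[predictor]] - mean(d[[predictor]])) / s
  }
  fml <- stats::reformulate(c(predictor, adjust_for), response = outcome)
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit))))
    stop_input("rank-deficient design (aliased coefficient)")
  est <- coef(fit)[[predictor]]
  ci <- suppressMessages(confint(fit, predictor, level = 0.95))
  p <- summary(fit)$coefficients[predictor, "Pr(>|t|)"]
  structure(list(B = est, ci95 = c(ci[1], ci[2]), p = p, n = nrow(d),
                 outcome = outcome, predictor = predictor,
                 adjust_for = adjust_for, fit = fit),
            class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("%s ~ %s%s: B = %.4f, 95%% CI [%.4f, %.4f], p = %.4g, n = %d\n",
              x$outcome, x$predictor,
              if (length(x$adjust_for)) paste0(" + ", paste(x$adjust_for, collapse = " + ")) else "",
              x$B, x$ci95[1], x$ci95[2], x$p, x$n))
  invisible(x)
}

#' Regression assumption diagnostics
#'
#' Residual normality (Shapiro-Wilk), heteroscedasticity (Breusch-Pagan via
#' `lmtest::bptest`), linearity (Ramsey RESET via `lmtest::resettest`), and
#' variance inflation factors (`car::vif`; only with >= 2 regressors). Each
#' is reported with a pass/warn status: warn when a test p-value falls below
#' 0.05 or any VIF exceeds 5. Diagnostics are advisory; no model is rejected
#' automatically.
#'
#' @param x an `assoc_fit` or an `lm` object.
#' @return data.frame with columns `check`, `statistic`, `p_value`, `status`.
#' @export
model_diagnostics <- function(x) {
  fit <- if (inherits(x, "assoc_fit")) x$fit else x
  if (!inherits(fit, "lm")) stop_input("x must be an 'assoc_fit' or 'lm'")
  res <- resid(fit)
  rows <- list()
  sw <- tryCatch(shapiro.test(res), error = function(e) NULL)
  rows$normality <- if (is.null(sw)) c(NA, NA) else c(unname(sw$statistic), sw$p.value)
  bp <- lmtest::bptest(fit)
  rows$heteroscedasticity <- c(unname(bp$statistic), bp$p.value)
  rt <- tryCatch(lmtest::resettest(fit), error = function(e) NULL)
  rows$linearity <- if (is.null(rt)) c(NA, NA) else c(unname(rt$statistic), rt$p.value)
  nreg <- length(coef(fit)) - 1L
  vif_max <- if (nreg >= 2) {
    v <- tryCatch(car::vif(fit), error = function(e) Inf)
    max(as.numeric(v))
  } else NA_real_
  out <- data.frame(
    check = c(names(rows), "multicollinearity"),
    statistic = c(vapply(rows, `[`, numeric(1), 1), vif_max),
    p_value = c(vapply(rows, `[`, numeric(1), 2), NA_real_),
    stringsAsFactors = FALSE
  )
  out$status <- ifelse(
    out$check == "multicollinearity",
    ifelse(is.na(out$statistic), "pass",
           ifelse(out$statistic > 5, "warn", "pass")),
    ifelse(!is.na(out$p_value) & out$p_value < 0.05, "warn", "pass")
  )
  rownames(out) <- NULL
  out
}

#' Run the full association suite
#'
#' Fits, for the cognitive composite and each domain z-score: univariate
#' models on age (years), PTA, the four wave I/V features, the I-V latency
#' difference and the log V/I amplitude ratio; the same models age-adjusted;
#' and repeats within each age group. Optionally adds the binary hearing
#' category as a predictor. ABR and hearing predictors are standardized to
#' sample z-units (age stays in years; the binary category stays 0/1). Rows
#' that fail (e.g. insufficient subgroup n) are kept with `NA` estimates and
#' the error message in `note`.
#'
#' @param scored scored cohort (see [score_cohort()]).
#' @param outcomes outcome columns; default composite plus all `z_` domains.
#' @param predictors predictor columns; default the auditory set present in
#'   the data.
#' @param subgroups fit within each age group in addition to the full sample.
#' @param hearing_binary also use `hearing_category` (0 = normal, 1 = loss)
#'   as a predictor.
#' @param diagnostics attach diagnostic warn counts per model.
#' @return tidy data.frame: one row per (outcome, predictor, adjustment,
#'   subgroup) with `n`, `B`, `ci_low`, `ci_high`, `p`, `diag_warnings`,
#'   `note`.
#' @export
run_association_suite <- function(scored, outcomes = NULL, predictors = NULL,
                                  subgroups = TRUE, hearing_binary = TRUE,
                                  diagnostics = TRUE) {
  if (is.null(outcomes)) {
    outcomes <- c("composite", grep("^z_", names(scored), value = TRUE))
  }
  if (is.null(predictors)) {
    predictors <- intersect(
      c("age", "pta", "wave_i_latency", "wave_i_amplitude",
        "wave_v_latency", "wave_v_amplitude", "iv_latency_difference",
        "log_vi_amplitude_ratio"),
      names(scored))
  }
  dat <- scored
  if (hearing_binary && "hearing_category" %in% names(dat)) {
    dat$hearing_loss <- as.numeric(dat$hearing_category == "loss")
    predictors <- c(predictors, "hearing_loss")
  }
  groups <- list(all = rep(TRUE, nrow(dat)))
  if (subgroups && "age_group" %in% names(dat)) {
    for (g in levels(dat$age_group)) {
      groups[[g]] <- !is.na(dat$age_group) & dat$age_group == g
    }
  }
  rows <- list()
  for (gname in names(groups)) {
    for (oc in outcomes) {
      for (pr in predictors) {
        for (adj in list(character(0), "age")) {
          if (pr == "age" && length(adj)) next
          zp <- !(pr %in% c("age", "hearing_loss"))
          res <- tryCatch(
            fit_linear_model(dat, oc, pr, adjust_for = adj,
                             z_predictor = zp, subset = groups[[gname]]),
            error = function(e) e)
          if (inherits(res, "error")) {
            rows[[length(rows) + 1L]] <- data.frame(
              subgroup = gname, outcome = oc, predictor = pr,
              adjusted = length(adj) > 0, n = NA_integer_, B = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
              diag_warnings = NA_integer_,
              note = conditionMessage(res), stringsAsFactors = FALSE)
          } else {
            dw <- if (diagnostics) {
              sum(model_diagnostics(res)$status == "warn")
            } else NA_integer_
            rows[[length(rows) + 1L]] <- data.frame(
              subgroup = gname, outcome = oc, predictor = pr,
              adjusted = length(adj) > 0, n = res$n, B = res$B,
              ci_low = res$ci95[1], ci_high = res$ci95[2], p = res$p,
              diag_warnings = dw, note = NA_character_,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare an outcome across age groups
#'
#' One-way general linear model (ANOVA F test) of the outcome on age group,
#' with pairwise group mean differences and Bonferroni-adjusted post-hoc
#' p-values (pooled-SD t tests).
#'
#' @param scored scored cohort with an `age_group` column (or supply `group`).
#' @param outcome outcome column name.
#' @param group grouping column name.
#' @return list with `F`, `df`, `p`, and `pairwise` (data.frame: `group1`,
#'   `group2`, `mean_diff`, `p_bonferroni`).
#' @export
compare_age_groups <- function(scored, outcome, group = "age_group") {
  if (!outcome %in% names(scored)) stop_input("missing outcome column: ", outcome)
  g <- droplevels(factor(scored[[group]]))
  y <- scored[[outcome]]
  keep <- !is.na(g) & !is.na(y)
  g <- droplevels(g[keep]); y <- y[keep]
  tab <- table(g)
  if (length(tab) < 2) stop_input("need at least 2 groups")
  if (any(tab < 2)) stop_input("each group needs at least 2 members")
  fit <- aov(y ~ g)
  s <- summary(fit)[[1]]
  means <- tapply(y, g, mean)
  pw <- pairwise.t.test(y, g, p.adjust.method = "bonferroni", pool.sd = TRUE)
  cmb <- which(!is.na(pw$p.value), arr.ind = TRUE)
  pairwise <- data.frame(
    group1 = rownames(pw$p.value)[cmb[, 1]],
    group2 = colnames(pw$p.value)[cmb[, 2]],
    mean_diff = means[rownames(pw$p.value)[cmb[, 1]]] -
      means[colnames(pw$p.value)[cmb[, 2]]],
    p_bonferroni = pw$p.value[cmb],
    stringsAsFactors = FALSE
  )
  rownames(pairwise) <- NULL
  list(F = s[["F value"]][1], df = c(s[["Df"]][1], s[["Df"]][2]),
       p = s[["Pr(>F)"]][1], pairwise = pairwise)
}
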