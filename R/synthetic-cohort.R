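# Synthetic cohort generator: participants with age, hearing, ABR wave
# features, and ten cognitive domain scores tied to a latent composite.

#' Default synthetic cohort parameters
#'
#' Returns the generating model for a synthetic adult cohort calibrated to a
#' cross-sectional ABR-cognition study design: three age groups (young 18-30,
#' middle-aged 31-59, elderly 60-92 years; n = 26/26/66), a pure-tone average
#' (PTA) that rises with age, wave V latency that lengthens and amplitude that
#' shrinks with age, age-independent wave I features, and a latent cognitive
#' composite that declines with age (-0.021 z/year marginally) and depends on
#' wave V latency (-0.101 z per z) and amplitude (+0.110 z per z) beyond age.
#'
#' The `cognition` age slope is the *marginal* composite-on-age slope: the
#' value an unadjusted regression of composite on age recovers. The direct age
#' coefficient used inside the generator is derived from it by subtracting the
#' ABR-mediated pathway, so that age-adjusted regressions on the (standardized)
#' wave V features recover `latency_slope` and `amplitude_slope`.
#'
#' @param seed integer seed stored with the parameters; every generation run
#'   is a pure function of `(params, seed)`.
#' @return A list of class `cohort_params` with components `group_sizes`,
#'   `age_ranges`, `pta_model`, `wave_v_latency_model`,
#'   `wave_v_amplitude_model`, `wave_i_model`, `cognition_model`,
#'   `domain_noise_sd`, `domains`, `missing_rate`, `female_fraction`, `seed`.
#' @export
#' @examples
#' p <- cohort_params()
#' p$group_sizes
cohort_params <- function(seed = 1L) {
  p <- structure(list(
    group_sizes = c(young = 26L, middle = 26L, elderly = 66L),
    age_ranges = list(young = c(18, 30), middle = c(31, 59),
                      elderly = c(60, 92)),
    # dB HL; calibrated so group means sit near 1.4 / 11-13 / 22 dB
    pta_model = list(intercept = -8.7, slope = 0.44, sd = 9),
    # ms; group means near 5.95 / 6.01 / 6.11
    wave_v_latency_model = list(intercept = 5.873, slope = 0.00334, sd = 0.28),
    # uV; group means near 0.30 / 0.25 / 0.19
    wave_v_amplitude_model = list(intercept = 0.353, slope = -0.0023, sd = 0.10),
    # age-independent wave I
    wave_i_model = list(latency_mean = 1.80, latency_sd = 0.26,
                        amplitude_mean = 0.10, amplitude_sd = 0.09),
    cognition_model = list(intercept = NA_real_,  # filled below: zero-mean composite
                           age_slope = -0.021,    # marginal, z per year
                           latency_slope = -0.101, # z per z of wave V latency
                           amplitude_slope = 0.110, # z per z of wave V amplitude
                           sd = 0.45),
    domain_noise_sd = 0.76,
    domains = default_domains(),
    missing_rate = 0,
    female_fraction = 66 / 118,
    seed = as.integer(seed)
  ), class = "cohort_params")
  am <- age_moments(p$group_sizes, p$age_ranges)
  p$cognition_model$intercept <- -p$cognition_model$age_slope * am$mean
  p
}

#' The ten cognitive domain measures
#'
#' Raw-score anchors (full-sample mean and SD in native units) and direction
#' flags for the ten measures of the cognitive battery. Time-based measures
#' (trail-making A/B, spatial-test reaction time) are lower-is-better; all
#' others higher-is-better.
#'
#' @return data.frame with columns `measure`, `mean`, `sd`, `higher_better`.
#' @export
default_domains <- function() {
  data.frame(
    measure = c("word_learning", "delayed_recall", "word_recognition",
                "animal_fluency", "tmt_a", "tmt_b", "fmt_accuracy",
                "fmt_rt", "visual_discrimination", "sdmt"),
    mean = c(22.10, 7.08, 19.52, 22.81, 26.77, 66.65, 10.10,
             8150.77, 15.97, 52.42),
    sd = c(3.59, 2.01, 1.31, 5.65, 8.84, 27.33, 2.87,
           2221.63, 1.82, 11.63),
    higher_better = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                      FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

validate_cohort_params <- function(p) {
  if (!inherits(p, "cohort_params")) stop_param("params must be a 'cohort_params' object")
  if (any(p$group_sizes < 1)) stop_param("group_sizes: all group sizes must be >= 1")
  sds <- c(pta = p$pta_model$sd, wave_v_latency = p$wave_v_latency_model$sd,
           wave_v_amplitude = p$wave_v_amplitude_model$sd,
           wave_i_latency = p$wave_i_model$latency_sd,
           wave_i_amplitude = p$wave_i_model$amplitude_sd,
           cognition = p$cognition_model$sd, domain_noise = p$domain_noise_sd)
  bad <- names(sds)[sds < 0]
  if (length(bad)) stop_param("negative SD in field(s): ", paste(bad, collapse = ", "))
  r <- do.call(rbind, p$age_ranges)
  if (any(r[, 2] < r[, 1])) stop_param("age_ranges: each range must be ordered min <= max")
  if (nrow(r) > 1 && any(r[-1, 1] <= r[-nrow(r), 2]))
    stop_param("age_ranges: ranges must be non-overlapping and increasing")
  if (p$missing_rate < 0 || p$missing_rate >= 1)
    stop_param("missing_rate must be in [0, 1)")
  invisible(p)
}

# Deterministic quantities implied by the generating model: population SDs of
# the wave V features, the direct (ABR-pathway-removed) age coefficient, and
# the latent composite's population variance.
derive_cohort_truth <- function(p) {
  am <- age_moments(p$group_sizes, p$age_ranges)
  lat <- p$wave_v_latency_model; amp <- p$wave_v_amplitude_model
  cg <- p$cognition_model
  sd_lat <- sqrt(lat$slope^2 * am$var + lat$sd^2)
  sd_amp <- sqrt(amp$slope^2 * am$var + amp$sd^2)
  # d E[z_feature]/d age
  dz_lat <- if (sd_lat > 0) lat$slope / sd_lat else 0
  dz_amp <- if (sd_amp > 0) amp$slope / sd_amp else 0
  b_age_direct <- cg$age_slope - cg$latency_slope * dz_lat -
    cg$amplitude_slope * dz_amp
  # population variance of the latent composite
  c_ll <- if (sd_lat > 0) 1 else 0
  c_aa <- if (sd_amp > 0) 1 else 0
  cov_la <- dz_lat * dz_amp * am$var
  var_c <- b_age_direct^2 * am$var + cg$latency_slope^2 * c_ll +
    cg$amplitude_slope^2 * c_aa +
    2 * b_age_direct * cg$latency_slope * dz_lat * am$var +
    2 * b_age_direct * cg$amplitude_slope * dz_amp * am$var +
    2 * cg$latency_slope * cg$amplitude_slope * cov_la +
    cg$sd^2
  list(age_mean = am$mean, age_var = am$var,
       sd_wave_v_latency = sd_lat, sd_wave_v_amplitude = sd_amp,
       b_age_direct = b_age_direct, composite_var = var_c,
       domain_scale = sqrt(var_c + p$domain_noise_sd^2))
}

#' Generate a synthetic cohort
#'
#' Draws one participant table from the generating model in `params`: ages
#' uniform within each group's range; PTA and wave V features linear in age
#' with Gaussian residuals; wave I features age-independent; a latent
#' cognitive composite linear in age and in the population-standardized wave V
#' features; and ten raw domain scores, each a shared-composite factor plus
#' independent noise mapped onto its native scale (time-based measures
#' inverted). The same `(params, seed)` always yields an identical table.
#'
#' @param params a [cohort_params()] object.
#' @param seed optional integer overriding `params$seed`.
#' @return A list with `cohort` (data.frame, one row per participant) and
#'   `truth` (the realized parameters, derived model constants, and the
#'   per-participant latent composite).
#' @export
#' @examples
#' g <- generate_cohort(cohort_params(seed = 7))
#' nrow(g$cohort)
generate_cohort <- function(params = cohort_params(), seed = NULL) {
  validate_cohort_params(params)
  seed <- seed %||% params$seed
  der <- derive_cohort_truth(params)
  with_seed(seed, {
    groups <- rep(names(params$group_sizes), params$group_sizes)
    n <- length(groups)
    age <- numeric(n)
    for (g in names(params$group_sizes)) {
      idx <- groups == g
      r <- params$age_ranges[[g]]
      age[idx] <- runif(sum(idx), r[1], r[2])
    }
    sex <- ifelse(rbinom(n, 1, params$female_fraction) == 1, "F", "M")
    pm <- params$pta_model
    pta <- pm$intercept + pm$slope * age + rnorm(n, 0, pm$sd)
    pta <- pmax(pta, -10)
    lm_ <- params$wave_v_latency_model
    wv_lat <- lm_$intercept + lm_$slope * age + rnorm(n, 0, lm_$sd)
    am_ <- params$wave_v_amplitude_model
    wv_amp <- pmax(am_$intercept + am_$slope * age + rnorm(n, 0, am_$sd), 0.005)
    wi <- params$wave_i_model
    wi_lat <- rnorm(n, wi$latency_mean, wi$latency_sd)
    wi_amp <- pmax(rnorm(n, wi$amplitude_mean, wi$amplitude_sd), 0.005)

    cg <- params$cognition_model
    z_lat <- if (der$sd_wave_v_latency > 0) {
      (wv_lat - (lm_$intercept + lm_$slope * der$age_mean)) / der$sd_wave_v_latency
    } else rep(0, n)
    z_amp <- if (der$sd_wave_v_amplitude > 0) {
      (wv_amp - (am_$intercept + am_$slope * der$age_mean)) / der$sd_wave_v_amplitude
    } else rep(0, n)
    mu_c <- cg$intercept + cg$age_slope * der$age_mean
    latent <- mu_c + der$b_age_direct * (age - der$age_mean) +
      cg$latency_slope * z_lat + cg$amplitude_slope * z_amp +
      rnorm(n, 0, cg$sd)

    dom <- params$domains
    scores <- matrix(NA_real_, n, nrow(dom),
                     dimnames = list(NULL, dom$measure))
    for (k in seq_len(nrow(dom))) {
      u <- (latent - mu_c + rnorm(n, 0, params$domain_noise_sd)) / der$domain_scale
      dirk <- if (dom$higher_better[k]) 1 else -1
      scores[, k] <- dom$mean[k] + dom$sd[k] * dirk * u
    }
    if (params$missing_rate > 0) {
      miss <- matrix(runif(n * nrow(dom)) < params$missing_rate, n)
      scores[miss] <- NA_real_
    }

    cohort <- data.frame(
      id = sprintf("S%03d", seq_len(n)), group = groups, age = age, sex = sex,
      pta = pta, wave_i_latency = wi_lat, wave_i_amplitude = wi_amp,
      wave_v_latency = wv_lat, wave_v_amplitude = wv_amp,
      stringsAsFactors = FALSE
    )
    cohort <- cbind(cohort, as.data.frame(scores))
    truth <- list(params = params, seed = seed, derived = der,
                  latent_composite = latent)
    list(cohort = cohort, truth = truth)
  })
}
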