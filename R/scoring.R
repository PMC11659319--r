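# Hearing and cognitive scoring: pure-tone average / better ear,
# direction-adjusted z-scores, the cognitive composite, and categorical
# groupings.

PTA_FREQS <- c(500, 1000, 2000, 4000)

#' Pure-tone average and better ear
#'
#' PTA is the arithmetic mean of the audiometric thresholds at 0.5, 1, 2 and
#' 4 kHz per ear; the better ear is the one with the smaller PTA. A tie goes
#' to the right ear (noted in the result). An ear whose required thresholds
#' are missing is skipped; at least one complete ear is required.
#'
#' @param left,right named numeric vectors of thresholds in dB HL; names are
#'   frequencies in Hz and must include 500, 1000, 2000, 4000. Either ear may
#'   be `NULL`.
#' @return list with `pta` (dB HL), `ear` (`"left"`/`"right"`), `note`.
#' @export
#' @examples
#' compute_pta_better_ear(left = c(`500` = 10, `1000` = 20, `2000` = 20, `4000` = 30),
#'                        right = c(`500` = 20, `1000` = 25, `2000` = 25, `4000` = 35))
compute_pta_better_ear <- function(left = NULL, right = NULL) {
  ear_pta <- function(thr) {
    if (is.null(thr)) return(NA_real_)
    vals <- unname(thr[as.character(PTA_FREQS)])
    if (anyNA(vals)) {
      return(structure(NA_real_,
                       missing = PTA_FREQS[is.na(vals)]))
    }
    mean(vals)
  }
  pl <- ear_pta(left)
  pr <- ear_pta(right)
  if (is.na(pl) && is.na(pr)) {
    miss <- unique(c(attr(pl, "missing"), attr(pr, "missing")))
    stop_input("no ear has complete thresholds at required frequencies: ",
               paste(if (length(miss)) miss else PTA_FREQS, collapse = ", "), " Hz")
  }
  if (is.na(pr) || (!is.na(pl) && pl < pr)) {
    return(list(pta = as.numeric(pl), ear = "left", note = NA_character_))
  }
  note <- if (!is.na(pl) && pl == pr) "tie: right ear used" else NA_character_
  list(pta = as.numeric(pr), ear = "right", note = note)
}

#' Age group and hearing category
#'
#' Age groups: young 18-30, middle-aged 31-59, elderly >= 60 years. Hearing
#' loss iff PTA >= 20 dB HL (strictly below 20 is normal hearing).
#' Vectorized.
#'
#' @param age years (>= 18).
#' @param pta dB HL (optional, `NA` allowed).
#' @return data.frame with `age_group` (factor young/middle/elderly) and
#'   `hearing_category` (factor normal/loss, `NA` where `pta` is `NA`).
#' @export
categorize_participant <- function(age, pta = NA_real_) {
  if (any(age < 18, na.rm = TRUE)) stop_input("age must be >= 18 years")
  grp <- cut(age, breaks = c(18, 30, 59, Inf), include.lowest = TRUE,
             labels = c("young", "middle", "elderly"))
  hc <- factor(ifelse(is.na(pta), NA, ifelse(pta >= 20, "loss", "normal")),
               levels = c("normal", "loss"))
  data.frame(age_group = grp, hearing_category = hc)
}

#' Direction-adjusted z-scores and the cognitive composite
#'
#' Each raw measure is standardized against the analyzed sample
#' (`z = (x - mean) / sd`, `n - 1` denominator) and sign-flipped for
#' lower-is-better measures so that higher z always means better performance.
#' The composite is the mean over a participant's available z-scores when at
#' least `min_available` of the 10 are present; otherwise the participant is
#' flagged excluded (`composite = NA`).
#'
#' @param cohort data.frame containing the raw measure columns.
#' @param battery data.frame as [default_domains()] (`measure`,
#'   `higher_better`; the anchor columns are ignored here).
#' @param min_available minimum non-missing measures for a composite.
#' @return the cohort with added `z_<measure>` columns, `composite`, and
#'   logical `composite_excluded`.
#' @export
build_cognitive_scores <- function(cohort, battery = default_domains(),
                                   min_available = 8L) {
  if (nrow(cohort) < 2) stop_input("need at least 2 participants to z-score")
  missing_cols <- setdiff(battery$measure, names(cohort))
  if (length(missing_cols))
    stop_input("cohort lacks measure column(s): ", paste(missing_cols, collapse = ", "))
  zmat <- matrix(NA_real_, nrow(cohort), nrow(battery),
                 dimnames = list(NULL, paste0("z_", battery$measure)))
  for (k in seq_len(nrow(battery))) {
    x <- cohort[[battery$measure[k]]]
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0)
      stop_input("zero-variance measure: ", battery$measure[k])
    z <- (x - mean(x, na.rm = TRUE)) / s
    if (!battery$higher_better[k]) z <- -z
    zmat[, k] <- z
  }
  n_avail <- rowSums(!is.na(zmat))
  composite <- ifelse(n_avail >= min_available,
                      rowMeans(zmat, na.rm = TRUE), NA_real_)
  out <- cbind(cohort, as.data.frame(zmat))
  out$composite <- composite
  out$composite_excluded <- n_avail < min_available
  out
}

#' Score a cohort end to end
#'
#' Adds cognitive z-scores and composite ([build_cognitive_scores()]),
#' age-group and hearing categories ([categorize_participant()]), and the
#' derived ABR composites (I-V latency difference; natural-log V/I amplitude
#' ratio) when wave columns are present.
#'
#' @param cohort canonical cohort data.frame (see [read_cohort()]).
#' @param battery cognitive battery definition.
#' @return scored cohort data.frame.
#' @export
score_cohort <- function(cohort, battery = default_domains()) {
  out <- build_cognitive_scores(cohort, battery)
  cats <- categorize_participant(out$age, out$pta %||% rep(NA_real_, nrow(out)))
  out$age_group <- cats$age_group
  out$hearing_category <- cats$hearing_category
  has <- function(...) all(c(...) %in% names(out))
  if (has("wave_i_latency", "wave_v_latency") &&
      !"iv_latency_difference" %in% names(out)) {
    out$iv_latency_difference <- out$wave_v_latency - out$wave_i_latency
  }
  if (has("wave_i_amplitude", "wave_v_amplitude") &&
      !"log_vi_amplitude_ratio" %in% names(out)) {
    ok <- !is.na(out$wave_i_amplitude) & !is.na(out$wave_v_amplitude) &
      out$wave_i_amplitude > 0 & out$wave_v_amplitude > 0
    out$log_vi_amplitude_ratio <- ifelse(ok,
      log(out$wave_v_amplitude / out$wave_i_amplitude), NA_real_)
  }
  out
}
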